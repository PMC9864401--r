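# 12C,6,12
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,135.166910719491
0.040000000000000001,230.08223751116404
0.059999999999999998,346.93404496116455
0.080000000000000002,446.05158202678228
0.10000000000000001,522.00494914536284
0.14999999999999999,638.80402393618022
0.20000000000000001,702.07388075458016
0.29999999999999999,747.68773278836068
0.5,757.990613750948
0.69999999999999996,730.85517974765889
1,641.66444053712087
1.5,558.60145078045139
2,480.56201980850153
3,381.84563662545804
5,273.42387922180819
7,213.15540969518077
10,163.07480708657846
15,118.51148830732336
20,93.768789800190305
30,67.524632440234654
50,44.819408577876672
70,34.41593703351873
100,26.240395448620159
150,19.601999826291287
200,16.171199984988835
250,14.079599997833133
300,12.671999999553755
400,10.907999999961014
500,9.8747999999935203
700,8.7479999999994451
1000,7.9595999999999369
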