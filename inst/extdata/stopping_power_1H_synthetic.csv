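# 1H,1,1
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,64
0.040000000000000001,73
0.059999999999999998,79
0.080000000000000002,81
0.10000000000000001,80
0.14999999999999999,73
0.20000000000000001,66
0.29999999999999999,54.5
0.5,41.700000000000003
0.69999999999999996,34.300000000000004
1,26.080000000000002
1.5,19.900000000000002
2,15.91
3,11.710000000000001
5,7.9100000000000001
7,6.04
10,4.5670000000000002
15,3.3000000000000003
20,2.6070000000000002
30,1.8760000000000003
50,1.2450000000000001
70,0.95600000000000007
100,0.72889999999999999
150,0.5445000000000001
200,0.44920000000000004
250,0.3911
300,0.35200000000000004
400,0.30299999999999999
500,0.27429999999999999
700,0.24300000000000002
1000,0.22109999999999999
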