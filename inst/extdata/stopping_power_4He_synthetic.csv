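# 4He,2,4
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,49.195073679099181
0.040000000000000001,78.339293676439212
0.059999999999999998,110.32435636544848
0.080000000000000002,134.24687264110702
0.10000000000000001,149.9546825280969
0.14999999999999999,167.14800716334562
0.20000000000000001,170.81039316511394
0.29999999999999999,162.8865150631845
0.5,142.4571331043901
0.69999999999999996,124.52571562982251
1,98.945721898645445
1.5,77.776165769439729
2,62.90536272420421
3,46.668931745704775
5,31.621292533006343
7,24.15672666578886
10,18.267609554626087
15,13.199977233952854
20,10.42799779050751
30,7.5039999498545837
50,4.9799999998332094
70,3.8239999999978989
100,2.9155999999999884
150,2.1780000000000004
200,1.7968000000000002
250,1.5644
300,1.4080000000000001
400,1.212
500,1.0972
700,0.97199999999999998
1000,0.88439999999999996
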