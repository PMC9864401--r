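# 10Be,4,10
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,95.078943111063779
0.040000000000000001,158.63035704829628
0.059999999999999998,234.26595752190161
0.080000000000000002,296.12177949068024
0.10000000000000001,341.542466735159
0.14999999999999999,405.75263095235607
0.20000000000000001,435.52340510939649
0.29999999999999999,447.00232140192759
0.5,430.24686566040873
0.69999999999999996,399.96196713530111
1,337.55677480755446
1.5,281.28007504958043
2,235.11592739512162
3,180.36619490231394
5,125.05069448710174
7,96.183657293711804
10,72.964108547924255
15,52.784028293818203
20,41.708632199586049
30,30.015725350556075
50,19.919993516505787
70,15.295999626149865
100,11.662399986993305
150,8.7119999998027797
200,7.187199999991539
250,6.2575999999993011
300,5.6319999999999091
400,4.8479999999999954
500,4.3887999999999998
700,3.8879999999999999
1000,3.5375999999999999
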