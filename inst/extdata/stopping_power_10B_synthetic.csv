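# 10B,5,10
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,115.68587038086402
0.040000000000000001,195.26623016427334
0.059999999999999998,291.86034508357278
0.080000000000000002,372.55524902087438
0.10000000000000001,433.31150745252341
0.14999999999999999,523.60939175456042
0.20000000000000001,569.6743623382672
0.29999999999999999,597.10337510886279
0.5,591.78622346202292
0.69999999999999996,561.45473226206184
1,484.2738843151904
1.5,413.20864364807227
2,350.70377795722692
3,273.96005626355918
5,192.97948110830646
7,149.35762014945129
10,113.71853623440025
15,82.41583028916898
20,65.153694272434691
30,46.897652168378194
50,31.124912102134179
70,23.899992750827025
100,18.222499613558892
150,13.6124999899579
200,11.229999999351699
250,9.7774999999258139
300,8.7999999999873744
400,7.5749999999991795
500,6.8574999999998907
700,6.074999999999994
1000,5.5274999999999999
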