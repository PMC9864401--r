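# 7Li,3,7
energy_MeV_per_n,stopping_keV_per_um
0.025000000000000001,73.055327328821122
0.040000000000000001,119.79702590470478
0.059999999999999998,173.80097108870822
0.080000000000000002,216.55996706006835
0.10000000000000001,246.75245303266271
0.14999999999999999,286.04455611130857
0.20000000000000001,301.19557410365434
0.29999999999999999,300.20813087673179
0.5,277.75834606728597
0.69999999999999996,251.46534353485234
1,206.56291622462876
1.5,167.41710609776615
2,137.62858219208428
3,103.68190309999562
5,70.901772921404259
7,54.288462947911817
10,41.08978203132564
15,29.698600921821399
20,23.462776880136431
30,16.883988517491616
50,11.204999866110215
70,8.6039999955339646
100,6.5600999999191005
150,4.9004999999994627
200,4.0427999999999882
250,3.5198999999999994
300,3.1680000000000001
400,2.7269999999999999
500,2.4687000000000001
700,2.1869999999999998
1000,1.9899
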