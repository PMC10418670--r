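# molecule: 1M5NI
# channel: attachment
# threshold_eV: 1.5
# units: 1e-20 m2
# note: zeros mark cells left blank in the source table (channel closed below threshold or negligible)
energy_eV,sigma_1e-20_m2
0.1,0.000
0.2,0.000
0.3,0.000
0.4,0.000
0.5,0.000
0.7,0.000
1.0,0.000
1.5,2.390
2.0,14.500
3.0,4.120
4.0,0.425
5.0,1.740
7.0,0.136
10.0,0.100
15.0,0.100
20.0,0.000
30.0,0.000
40.0,0.000
50.0,0.000
70.0,0.000
100.0,0.000
150.0,0.000
200.0,0.000
300.0,0.000
400.0,0.000
500.0,0.000
700.0,0.000
1000.0,0.000
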