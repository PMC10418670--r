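# molecule: 1M5NI
# channel: ionization
# threshold_eV: 15
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
1.5,0.000
2.0,0.000
3.0,0.000
4.0,0.000
5.0,0.000
7.0,0.000
10.0,0.000
15.0,0.328
20.0,3.110
30.0,9.520
40.0,12.600
50.0,13.700
70.0,12.500
100.0,13.900
150.0,12.600
200.0,11.300
300.0,9.410
400.0,8.040
500.0,7.060
700.0,5.680
1000.0,4.420
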