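# molecule: 1M5NI
# channel: vibrational
# threshold_eV: 0.7
# units: 1e-20 m2
# note: zeros mark cells left blank in the source table (channel closed below threshold or negligible)
energy_eV,sigma_1e-20_m2
0.1,0.00
0.2,0.00
0.3,0.00
0.4,0.00
0.5,0.00
0.7,0.10
1.0,3.28
1.5,11.90
2.0,20.30
3.0,20.00
4.0,17.30
5.0,13.90
7.0,14.20
10.0,0.00
15.0,0.00
20.0,0.00
30.0,0.00
40.0,0.00
50.0,0.00
70.0,0.00
100.0,0.00
150.0,0.00
200.0,0.00
300.0,0.00
400.0,0.00
500.0,0.00
700.0,0.00
1000.0,0.00
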