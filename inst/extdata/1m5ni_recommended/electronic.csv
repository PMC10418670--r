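# molecule: 1M5NI
# channel: electronic
# threshold_eV: 4
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
4.0,0.100
5.0,0.257
7.0,1.070
10.0,10.100
15.0,13.700
20.0,15.200
30.0,13.800
40.0,11.500
50.0,9.290
70.0,11.500
100.0,4.780
150.0,3.830
200.0,3.380
300.0,2.620
400.0,2.270
500.0,2.040
700.0,1.740
1000.0,1.430
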