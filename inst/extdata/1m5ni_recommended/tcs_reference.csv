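# molecule: 1M5NI
# channel: tcs_reference
# threshold_eV: 0
# units: 1e-20 m2
# note: printed SUM column; the 70 eV row is internally inconsistent with its own channel entries (known anomaly)
energy_eV,sigma_1e-20_m2
0.1,390.00
0.2,214.00
0.3,162.00
0.4,138.00
0.5,122.00
0.7,104.00
1.0,90.10
1.5,86.50
2.0,98.20
3.0,79.10
4.0,70.70
5.0,68.50
7.0,69.80
10.0,76.00
15.0,74.50
20.0,73.20
30.0,70.10
40.0,66.40
50.0,61.60
70.0,66.40
100.0,47.80
150.0,40.70
200.0,35.90
300.0,29.20
400.0,24.89
500.0,21.80
700.0,17.70
1000.0,13.80
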