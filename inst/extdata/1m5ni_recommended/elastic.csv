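# molecule: 1M5NI
# channel: elastic
# threshold_eV: 0
# units: 1e-20 m2
# note: recommended elastic ICS
energy_eV,sigma_1e-20_m2
0.1,390.00
0.2,214.00
0.3,162.00
0.4,138.00
0.5,122.00
0.7,104.00
1.0,86.80
1.5,72.20
2.0,63.30
3.0,55.00
4.0,52.90
5.0,52.50
7.0,54.40
10.0,65.80
15.0,60.50
20.0,54.90
30.0,46.80
40.0,42.30
50.0,38.60
70.0,33.60
100.0,29.10
150.0,24.30
200.0,21.20
300.0,17.10
400.0,14.60
500.0,12.70
700.0,10.20
1000.0,7.95
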