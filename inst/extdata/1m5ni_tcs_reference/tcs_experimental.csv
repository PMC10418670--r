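# molecule: 1M5NI
# channel: tcs_experimental
# threshold_eV: 0
# units: 1e-20 m2
# note: transmission-measured TCS, uncorrected
energy_eV,sigma_1e-20_m2
1.0,84.4
1.2,81.8
1.4,78.0
1.5,80.4
1.6,86.3
1.8,90.2
2.0,92.6
2.1,89.2
2.2,86.8
2.3,82.3
2.4,78.8
2.6,74.7
2.8,74.0
2.9,75.7
3.0,76.7
3.2,76.1
3.4,75.5
3.6,72.8
3.8,68.5
4.0,68.1
4.1,66.0
4.2,63.2
4.4,65.0
4.6,65.9
4.8,65.9
5.0,65.3
5.2,64.6
5.4,63.5
5.6,62.4
5.8,64.5
6.0,66.9
6.2,70.4
6.4,67.6
6.6,64.4
6.8,68.6
7.0,68.3
7.2,65.1
7.4,66.8
7.6,68.4
7.8,67.8
8.0,69.7
8.2,67.6
8.4,66.4
8.6,62.9
8.8,64.8
9.0,65.7
9.2,67.3
9.5,64.7
9.8,67.2
10.0,73.2
10.5,71.4
11.0,74.2
12.0,71.8
13.0,72.0
14.0,71.6
16.0,71.5
18.0,70.5
20.0,70.7
22.0,69.1
25.0,69.0
30.0,67.9
35.0,66.4
40.0,64.3
45.0,62.7
50.0,59.7
55.0,57.9
60.0,56.3
65.0,53.9
70.0,52.1
80.0,49.6
90.0,47.9
100.0,46.2
120.0,42.6
150.0,39.3
200.0,34.8
250.0,31.3
300.0,27.6
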