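energy_eV,species,mass_u,probability
3.1,NO2-,46,0.58000000000
3.1,CN-,26,0.12870967742
3.1,CNO-,42,0.06129032258
3.1,C2N2Hx-,53,0.04600000000
3.1,C3N2Hx-,65,0.04600000000
3.1,C4N2Hx-,77,0.04600000000
3.1,M-NO,97,0.04600000000
3.1,M-OH/CH3,111,0.04600000000
4.7,NO2-,46,0.35000000000
4.7,CN-,26,0.21000000000
4.7,CNO-,42,0.10000000000
4.7,C2N2Hx-,53,0.06800000000
4.7,C3N2Hx-,65,0.06800000000
4.7,C4N2Hx-,77,0.06800000000
4.7,M-NO,97,0.06800000000
4.7,M-OH/CH3,111,0.06800000000
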