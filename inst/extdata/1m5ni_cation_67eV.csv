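"species","mass_u","relative_intensity"
"C4H5N3O2+ (1M5NI parent ion)",127,1
"C4H2N3O2+ (1M5NI-3H)",124,0.415
"C4H4N2O2+ (1M5NI-NH)",112,0.0564
"C4HNO (acrylonitrile-ketone)",84,0.152
"C2H5NO2 (glycine)",75,0.0978
"C2H3N3 (triazole)",69,0.137
"CH4NO (hydroxymethyl-amino-oxy radical)",62,0.09
"C2H4N2 (diazoethane)",56,0.571
"C3HN (cyanoacetylene)",51,0.139
"H2NO2+ (nitronium)",48,0.124
"CH3NO+ (formaldoxime)",45,0.633
"C2OH2+ (ketene)",42,0.23
"C2N (carbon cyanide radical)",38,0.072
"H3NO (hydroxylamine)",33,0.201
"CHO (formyl radical)",29,0.768
"H2O+ (water)",18,0.0512
"NH (imidogen)",15,0.349
"C (carbon)",12,0.0435
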