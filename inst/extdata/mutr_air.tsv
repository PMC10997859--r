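# kind: mass_energy_transfer_air | source: NIST standard reference compilation (Hubbell & Seltzer), mass energy-absorption coefficients of dry air near sea level; radiative losses are negligible below 160 keV so these equal the mass energy-transfer coefficients at the accuracy documented in the package vignette | units: energy keV, value cm2/g
# note: the argon K edge at 3.2029 keV is carried as a doubled node; interpolation must not straddle it
1.0	3599.0
1.5	1188.0
2.0	526.2
3.0	161.4
3.20289	133.0
3.20291	146.0
4.0	76.36
5.0	39.31
6.0	22.70
8.0	9.446
10.0	4.742
15.0	1.334
20.0	0.5389
30.0	0.1537
40.0	0.06833
50.0	0.04098
60.0	0.03041
80.0	0.02407
100.0	0.02325
150.0	0.02496
200.0	0.02672
300.0	0.02872
400.0	0.02949
500.0	0.02966
600.0	0.02953
800.0	0.02882
1000.0	0.02789
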