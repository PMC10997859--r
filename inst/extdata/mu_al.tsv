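# kind: total_attenuation_al | source: NIST XCOM photon cross-section database, total mass attenuation coefficient of aluminium including coherent scattering | units: energy keV, value cm2/g | density_g_cm3: 2.699 (converted to linear attenuation 1/mm on load)
# note: the aluminium K edge at 1.5596 keV is carried as a doubled node; interpolation must not straddle it
1.0	1185.0
1.5	402.2
1.55959	362.1
1.55961	3957.0
2.0	2263.0
3.0	788.0
4.0	360.5
5.0	193.4
6.0	115.3
8.0	50.33
10.0	26.23
15.0	7.955
20.0	3.441
30.0	1.128
40.0	0.5685
50.0	0.3681
60.0	0.2778
80.0	0.2018
100.0	0.1704
150.0	0.1378
200.0	0.1223
300.0	0.1042
400.0	0.09276
500.0	0.08445
600.0	0.07802
800.0	0.06841
1000.0	0.06146
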