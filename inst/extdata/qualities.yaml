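# IEC 61267 / IAEA TRS-457 constants defining the RQR and RQA standard
# radiation qualities.  These are fixture input, user-editable: nominal tube
# voltage (practical peak voltage, kV), reference first half-value layer
# (mm Al), nominal homogeneity coefficient (RQR), and for the RQA series the
# fixed additional aluminium filtration (mm) applied on top of the
# established parent RQR beam.
schema_version: 1
rqr:
  RQR 2:  {nominal_kv: 40,  hvl_ref: 1.42, nominal_h: 0.81}
  RQR 3:  {nominal_kv: 50,  hvl_ref: 1.78, nominal_h: 0.76}
  RQR 4:  {nominal_kv: 60,  hvl_ref: 2.19, nominal_h: 0.74}
  RQR 5:  {nominal_kv: 70,  hvl_ref: 2.58, nominal_h: 0.71}
  RQR 6:  {nominal_kv: 80,  hvl_ref: 3.01, nominal_h: 0.69}
  RQR 7:  {nominal_kv: 90,  hvl_ref: 3.48, nominal_h: 0.68}
  RQR 8:  {nominal_kv: 100, hvl_ref: 3.97, nominal_h: 0.68}
  RQR 9:  {nominal_kv: 120, hvl_ref: 5.00, nominal_h: 0.68}
  RQR 10: {nominal_kv: 150, hvl_ref: 6.57, nominal_h: 0.72}
rqa:
  RQA 2:  {parent: RQR 2,  added_al: 4.0}
  RQA 3:  {parent: RQR 3,  added_al: 10.0}
  RQA 4:  {parent: RQR 4,  added_al: 16.0}
  RQA 5:  {parent: RQR 5,  added_al: 21.0}
  RQA 6:  {parent: RQR 6,  added_al: 26.0}
  RQA 7:  {parent: RQR 7,  added_al: 30.0}
  RQA 8:  {parent: RQR 8,  added_al: 34.0}
  RQA 9:  {parent: RQR 9,  added_al: 40.0}
  RQA 10: {parent: RQR 10, added_al: 45.0}
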