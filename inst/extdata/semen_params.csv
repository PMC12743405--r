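case,age,concentration_mln_per_ml,volume_ml,total_count_mln,normal_morphology_pct,total_motility_pct,progressive_motility_pct
K1,30,101.23,3.0,303.7,21.0,76.0,59.0
K2,26,48.93,2.5,122.3,4.0,74.0,66.0
K3,30,82.00,4.5,369.0,7.0,63.0,55.0
K4,25,80.25,3.8,305.0,4.0,57.0,48.0
K5,30,122.00,2.0,244.0,6.0,67.0,62.0
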