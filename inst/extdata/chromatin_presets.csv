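fraction,ab_pink_pct,ab_purple_pct,ab_navy_pct,ao_fragmented_pct,tunel_positive_pct
raw,75.47,13.77,10.76,21.03,5.54
SU,93.76,3.22,3.02,6.70,5.50
DGC,95.04,3.39,1.57,6.39,2.76
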