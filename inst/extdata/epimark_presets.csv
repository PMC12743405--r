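fraction,pos_5mC_pct,pos_5hmC_pct
raw,57.82,57.86
SU,64.87,64.61
DGC,61.59,61.79
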