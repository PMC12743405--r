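pair,fraction,mean_um,se_um
4-8,raw,1.888,0.03797
4-8,SU,2.073,0.03953
4-8,DGC,2.184,0.04091
7-9,raw,1.571,0.034
7-9,SU,1.707,0.03674
7-9,DGC,1.989,0.03991
18-X,raw,1.859,0.04028
18-X,SU,1.926,0.03576
18-X,DGC,1.853,0.03439
18-Y,raw,1.662,0.03512
18-Y,SU,1.858,0.03596
18-Y,DGC,1.739,0.03566
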