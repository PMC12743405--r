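chromosome,zone,raw_all,raw_hyper,raw_hypo,SU_all,SU_hyper,SU_hypo,DGC_all,DGC_hyper,DGC_hypo
4,a,9.33,11.50,8.67,11.83,11.50,13.17,16.67,15.33,17.83
4,m,60.17,58.00,61.50,60.83,59.33,59.83,60.83,59.00,59.17
4,b,30.50,30.50,29.83,27.33,29.17,27.00,22.50,25.67,23.00
7,a,21.23,22.97,20.20,23.17,24.33,27.67,26.83,25.33,26.50
7,m,62.03,58.77,64.70,58.17,58.67,55.83,53.33,55.00,53.33
7,b,16.73,18.27,15.10,18.50,16.67,16.50,19.83,19.67,20.17
8,a,10.17,11.83,9.67,16.67,17.00,15.50,18.33,17.17,17.67
8,m,58.33,58.17,58.67,57.00,55.33,56.33,57.17,59.00,55.33
8,b,31.50,30.00,31.67,26.33,27.67,28.17,24.50,23.83,27.00
9,a,16.03,17.97,17.83,17.67,20.33,18.50,23.17,24.33,24.00
9,m,68.83,66.70,67.90,65.17,63.83,65.50,60.67,61.50,59.50
9,b,15.13,15.33,14.27,16.83,15.83,15.67,16.17,14.00,16.50
18,a,20.43,20.65,20.40,18.75,18.25,19.00,20.67,21.67,21.33
18,m,59.22,57.25,58.25,59.25,60.33,56.75,58.67,58.00,57.58
18,b,20.35,22.10,21.35,22.00,21.42,24.25,20.67,20.33,21.08
18-X,a,21.13,22.17,19.03,19.00,18.17,18.33,20.00,21.17,21.00
18-X,m,56.13,55.27,57.30,56.33,58.50,57.17,59.67,58.00,57.83
18-X,b,22.73,22.57,23.67,24.67,23.33,24.50,20.33,20.83,21.17
18-Y,a,19.73,19.13,21.77,18.50,18.33,19.67,21.33,22.17,21.67
18-Y,m,62.30,59.23,59.20,62.17,62.17,56.33,57.67,58.00,57.33
18-Y,b,17.97,21.63,19.03,19.33,19.50,24.00,21.00,19.83,21.00
X,a,27.10,23.17,26.87,25.33,28.00,22.50,27.00,25.17,26.17
X,m,65.53,68.23,67.80,69.83,66.67,70.00,64.67,66.67,65.33
X,b,7.37,8.60,5.33,4.83,5.33,7.50,8.33,8.17,8.50
Y,a,19.30,18.10,21.03,19.67,21.00,19.67,20.67,22.67,21.50
Y,m,70.57,71.93,68.50,71.17,69.00,69.67,65.00,65.67,64.67
Y,b,10.13,9.97,10.47,9.17,10.00,10.67,14.33,11.67,13.83
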