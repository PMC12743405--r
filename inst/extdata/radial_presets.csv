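chromosome,axis,stat,raw_all,raw_hyper,raw_hypo,SU_all,SU_hyper,SU_hypo,DGC_all,DGC_hyper,DGC_hypo
4,d,mean,0.462,0.465,0.465,0.504,0.495,0.503,0.525,0.513,0.517
4,d,se,0.008,0.008,0.008,0.007,0.008,0.008,0.008,0.008,0.008
4,h,mean,0.163,0.162,0.163,0.173,0.173,0.170,0.179,0.176,0.169
4,h,se,0.004,0.004,0.004,0.004,0.004,0.004,0.004,0.004,0.004
7,d,mean,0.552,0.556,0.558,0.553,0.561,0.567,0.567,0.566,0.562
7,d,se,0.008,0.008,0.008,0.007,0.007,0.007,0.008,0.008,0.008
7,h,mean,0.141,0.149,0.141,0.140,0.143,0.144,0.150,0.150,0.149
7,h,se,0.004,0.004,0.004,0.003,0.003,0.003,0.004,0.004,0.004
8,d,mean,0.463,0.479,0.464,0.498,0.497,0.493,0.520,0.508,0.507
8,d,se,0.008,0.008,0.008,0.008,0.008,0.008,0.008,0.008,0.008
8,h,mean,0.142,0.156,0.136,0.151,0.150,0.159,0.169,0.162,0.157
8,h,se,0.004,0.004,0.004,0.003,0.004,0.004,0.004,0.004,0.004
9,d,mean,0.543,0.552,0.550,0.548,0.556,0.548,0.567,0.574,0.570
9,d,se,0.007,0.007,0.007,0.007,0.007,0.007,0.007,0.007,0.007
9,h,mean,0.132,0.143,0.136,0.138,0.144,0.139,0.150,0.149,0.146
9,h,se,0.004,0.004,0.003,0.003,0.003,0.003,0.004,0.004,0.004
18,d,mean,0.536,0.533,0.537,0.535,0.532,0.536,0.541,0.545,0.539
18,d,se,0.006,0.006,0.006,0.006,0.005,0.006,0.005,0.006,0.005
18,h,mean,0.152,0.151,0.151,0.169,0.170,0.169,0.157,0.156,0.160
18,h,se,0.003,0.003,0.003,0.003,0.002,0.003,0.002,0.002,0.003
18-X,d,mean,0.531,0.536,0.530,0.530,0.525,0.536,0.544,0.547,0.542
18-X,d,se,0.008,0.009,0.008,0.008,0.008,0.008,0.008,0.008,0.008
18-X,h,mean,0.148,0.155,0.149,0.173,0.172,0.171,0.156,0.157,0.160
18-X,h,se,0.004,0.004,0.004,0.004,0.003,0.004,0.004,0.003,0.004
18-Y,d,mean,0.542,0.530,0.544,0.541,0.539,0.535,0.539,0.544,0.535
18-Y,d,se,0.008,0.008,0.008,0.008,0.008,0.008,0.008,0.008,0.008
18-Y,h,mean,0.156,0.147,0.153,0.165,0.169,0.167,0.157,0.154,0.160
18-Y,h,se,0.004,0.004,0.004,0.004,0.004,0.004,0.003,0.003,0.004
X,d,mean,0.598,0.585,0.605,0.612,0.617,0.606,0.594,0.595,0.592
X,d,se,0.007,0.007,0.006,0.006,0.006,0.006,0.006,0.006,0.006
X,h,mean,0.130,0.124,0.134,0.148,0.147,0.153,0.129,0.133,0.134
X,h,se,0.004,0.003,0.004,0.003,0.003,0.003,0.003,0.003,0.003
Y,d,mean,0.563,0.562,0.573,0.584,0.587,0.577,0.568,0.573,0.565
Y,d,se,0.006,0.006,0.007,0.006,0.006,0.007,0.007,0.006,0.007
Y,h,mean,0.134,0.132,0.136,0.153,0.154,0.148,0.135,0.142,0.134
Y,h,se,0.004,0.004,0.004,0.003,0.003,0.003,0.003,0.003,0.003
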