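time_s,n_membrane_clathrin,n_clusters,total_area_um2
0,10,0,0
1,60,1,0.010
2,95,2,0.060
3,100,1,0.020
4,100,2,0.050
5,100,2,0.070
6,100,1,0.030
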