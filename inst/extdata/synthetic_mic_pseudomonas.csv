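mic_mg_per_L,count
0.25,2
0.5,12
1,120
2,480
4,900
8,650
16,310
32,150
64,60
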