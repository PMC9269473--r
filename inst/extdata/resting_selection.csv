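subject,condition,lower,upper,variance_pct,window_s,channels,channel_pct
S2,R1,0.028,0.272,60,5,47,78
S2,R2,0.131,0.211,50,2,39,65
S5,R1,0,0.156,30,5,41,72
S5,R2,0,0.197,40,4,29,49
S6,R1,0,0.138,30,4,35,61
S6,R2,0,0.134,40,4,48,80
S8,R1,0,0.098,30,4,33,54
S8,R2,0.032,0.102,30,4,27,44
S9,R1,0,0.241,50,3,50,91
S9,R2,0.135,0.273,67,2,48,83
S10,R1,0,0.088,30,4,45,75
S10,R2,0.006,0.086,30,4,47,77
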