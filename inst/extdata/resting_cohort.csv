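subject,condition,raw_s,clean_s,channels
S1,R1,305,46,51
S1,R2,311,172,53
S2,R1,308,235,59
S2,R2,314,256,60
S3,R1,284,46,59
S3,R2,204,43,58
S4,R1,192,101,54
S4,R2,278,123,53
S5,R1,308,205,57
S5,R2,306,155,59
S6,R1,308,230,57
S6,R2,311,226,60
S7,R1,353,135,54
S7,R2,313,212,55
S8,R1,315,197,61
S8,R2,319,231,62
S9,R1,189,145,55
S9,R2,184,116,58
S10,R1,303,172,60
S10,R2,328,240,61
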