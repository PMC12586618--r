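trial,point,row,col
S01_r1,posterior,80,96
S01_r1,anterior,80,36
S01_r1,upper_lip,66,26
S01_r1,lower_lip,92,26
S01_r2,posterior,81,97
S01_r2,anterior,81,37
S01_r2,upper_lip,67,27
S01_r2,lower_lip,93,27
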