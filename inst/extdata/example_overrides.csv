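trial,site,frame,run_index,threshold
S01_r1,TT-TD,12,2,
S01_r2,LA,,,65
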