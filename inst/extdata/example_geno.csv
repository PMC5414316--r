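id,M1,M2,M3,M4,M5
1,1,2,1,2,2
2,2,1,0,1,1
3,0,0,2,1,2
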