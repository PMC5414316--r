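id	value
1	1.97
2	2.12
3	-0.62
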