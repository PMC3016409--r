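0	M1
1	M2
2	M3
3	M4
4	M5
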