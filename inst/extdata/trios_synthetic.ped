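TR1	F	0	0	1	1	1	2	1	1	1	1	1	2	1	1
TR1	M	0	0	2	1	1	2	1	2	1	1	1	1	1	1
TR1	C1	F	M	0	2	1	1	1	1	1	1	1	1	1	1
TR2	F	0	0	1	1	2	2	1	2	1	2	1	1	2	2
TR2	M	0	0	2	1	1	2	1	1	1	1	1	2	2	2
TR2	C1	F	M	0	2	2	2	1	2	1	2	1	1	2	2
TR3	F	0	0	1	1	2	2	1	1	1	1	1	1	2	2
TR3	M	0	0	2	1	1	2	1	1	1	1	1	2	2	2
TR3	C1	F	M	0	2	1	2	1	1	1	1	1	2	2	2
TR4	F	0	0	1	1	2	2	1	1	1	2	1	1	2	2
TR4	M	0	0	2	1	1	2	1	1	1	1	1	2	2	2
TR4	C1	F	M	0	2	2	2	1	1	1	1	1	1	2	2
TR5	F	0	0	1	1	2	2	1	1	1	1	1	1	2	2
TR5	M	0	0	2	1	1	1	1	1	1	2	1	2	1	1
TR5	C1	F	M	0	2	1	2	1	1	1	1	1	1	1	2
TR6	F	0	0	1	1	1	2	1	1	1	1	1	1	1	2
TR6	M	0	0	2	1	1	1	1	1	1	2	2	2	1	2
TR6	C1	F	M	0	2	1	2	1	1	1	2	1	2	1	2
TR7	F	0	0	1	2	2	2	1	2	1	2	1	1	2	2
TR7	M	0	0	2	1	2	2	1	1	1	1	1	1	2	2
TR7	C1	F	M	0	2	2	2	1	2	1	2	1	1	2	2
TR8	F	0	0	1	1	1	2	1	2	1	1	2	2	1	1
TR8	M	0	0	2	1	1	1	1	2	1	2	1	2	2	2
TR8	C1	F	M	0	2	1	2	1	2	1	2	1	2	1	2
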