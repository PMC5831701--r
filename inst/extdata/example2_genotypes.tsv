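ID	m1	m2	m3	m4	m5
A1	0	1	0	1	0
A2	1	-1	-1	1	0
A3	-1	1	1	-1	0
A4	0	0	-1	-1	1
A5	0	1	0	1	0
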