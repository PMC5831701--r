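id	y
A1	-0.5
A2	-0.5
A3	0.0
A4	1.0
A5	-0.7
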