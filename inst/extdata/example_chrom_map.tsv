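snp_id	chrom
m1	1
m2	1
m3	1
m4	2
m5	2
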