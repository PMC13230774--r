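sample_id	chrom	pos	ref	alt	zygosity	dp	gq	ab
CASE_S1	1	1001	A	T	het	42	99	0.48
CASE_S1	1	1050	G	C	het	38	80	0.41
CASE_S2	1	1102	C	G	het	25	60	0.35
CASE_N1	X	5001	T	A	hemizygous	30	70	0.96
CTRL_1	1	1050	G	C	het	8	99	0.5
CTRL_2	1	1102	C	G	hom_alt	44	99	0.99
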