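sample_id	stratum	sex	pc1	pc2	pc3	pc4	pc5
CASE_S1	sCHD	female	0.1	-0.2	0.05	0.3	-0.1
CASE_S2	sCHD	male	-0.4	0.1	0.2	-0.3	0.2
CASE_N1	nsCHD	male	0.2	0.3	-0.1	0.1	0
CASE_N2	nsCHD	female	0	-0.1	0.4	0.2	-0.2
CTRL_1	control	male	-0.1	0.2	-0.3	0	0.1
CTRL_2	control	female	0.3	0	0.1	-0.1	0.3
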