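gene_id	symbol	chrom	loeuf	moeuf
GENE_A	GENEA	1	0.21	0.55
GENE_X	GENEX	X	0.33	0.4
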