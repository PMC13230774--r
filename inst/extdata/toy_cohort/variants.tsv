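chrom	pos	ref	alt	gene_id	consequence	lof_hc	cadd	revel	mvp	af_internal	af_gnomad_exomes	af_gnomad_genomes	af_rumc	af_inhouse
1	1001	A	T	GENE_A	stop_gained	TRUE	35			0.0001	0.0002		0.0001	
1	1050	G	C	GENE_A	missense	FALSE	27	0.62	0.41	0.0002	0.0001	0.0001		0.0002
1	1102	C	G	GENE_A	synonymous	FALSE				0.0003	0.0004	0.0002	0.0003	
X	5001	T	A	GENE_X	missense	FALSE	30	0.71	0.88	0.0001				
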