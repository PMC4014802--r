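motif_id	pattern	rbp_name	allowed_regions	group
fox	TGCATG	Fox-1/2	I2a|I2b	code_model
qk	ACTAAY	Qk	I1b|I2a	code_model
ptb	TCTTCT	Ptb1/2	I1a|I1b	code_model
cugbp	GTGTGT	Cugbp1/2	I1b|I2a	code_model
mbnl	YGCY	Mbnl1/2	I2a|I2b	code_model
nova	YCAY	Nova-1/2	I1b|I2a	code_model
tia	TTTTT	Tia1/Tiar	I2a	code_model
ese_srsf1	GAAGAA	ASF/SF2	A	code_model
ess_hnrnpa1	TAGGGT	hnRNPA1	A	code_model
gr_hnrnpfh	GGGGG	hnRNP-F/H	I1a|I2a	code_model
sc35	TGCTGTT	SC35	A	general_splicing
tra2	AGAAGA	Tra2a/b	A	general_splicing
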