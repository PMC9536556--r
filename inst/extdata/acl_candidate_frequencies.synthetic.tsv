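rsid	gene	chrom	pos	ref	alt	AFR	EUR
rs970547	COL12A1	chr6	75100000	C	T	0.0026	0.73
rs144399798	CATSPER2	chr15	43600000	C	T	0.0083	0.0003
rs76265595	KCNJ12	chr17	21200000	G	A	0	0.71
rs75029097	KCNJ12	chr17	21210000	G	A	0	0.32
rs77270326	KCNJ12	chr17	21220000	G	A	0.001	0.11
rs76684759	KCNJ12	chr17	21230000	T	G	0.002	0.017
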