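SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs1001	A	G	0.31	0.0793497	0.015	1.223e-07	547000
rs1002	T	C	0.38	-0.0542916	0.015	0.0002952	547000
rs1003	G	A	0.18	0.0292272	0.015	0.05136	547000
rs2001	A	C	0.22	0.0431048	0.015	0.004058	547000
rs2002	G	C	0.59	-0.0334379	0.015	0.0258	547000
rs2003	G	T	0.66	-0.0389056	0.015	0.009495	547000
rs2004	T	C	0.37	0.0302951	0.015	0.04342	547000
rs2005	A	G	0.55	0.0282658	0.015	0.05951	547000
rs2006	C	A	0.29	0.0540589	0.015	0.0003134	547000
rs2007	A	T	0.5	0.0344455	0.015	0.02165	547000
rs3001	T	C	0.45	0.00321539	0.015	0.8303	547000
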