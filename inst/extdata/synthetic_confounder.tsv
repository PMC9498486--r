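SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs1001	A	G	0.31	0.0515441	0.008	1.171e-10	212000
rs1002	C	T	0.62	0.020446	0.008	0.0106	212000
rs1003	G	A	0.18	-0.029022	0.008	0.0002859	212000
rs2001	A	C	0.22	0.139828	0.008	2.089e-68	212000
rs2002	C	G	0.41	0.109989	0.008	5.19e-43	212000
rs2003	G	T	0.66	-0.120407	0.008	3.408e-51	212000
rs2004	T	C	0.37	0.129142	0.008	1.278e-58	212000
rs2005	A	G	0.55	0.104071	0.008	1.089e-38	212000
rs2006	C	A	0.29	0.149363	0.008	8.615e-78	212000
rs2007	A	T	0.5	0.123273	0.008	1.421e-53	212000
rs2008	G	C	0.73	0.109942	0.008	5.634e-43	212000
rs3001	T	C	0.45	0.00325225	0.008	0.6844	212000
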