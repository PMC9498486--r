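SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs1001	A	G	0.31	0.120634	0.01	1.649e-33	460000
rs1002	C	T	0.62	0.102055	0.01	1.874e-24	460000
rs1003	G	A	0.18	0.0788204	0.01	3.221e-15	460000
rs2001	A	C	0.22	0.00461992	0.01	0.6441	460000
rs2002	C	G	0.41	-0.00254114	0.01	0.7994	460000
rs2003	G	T	0.66	0.000667247	0.01	0.9468	460000
rs2004	T	C	0.37	-0.00610856	0.01	0.5413	460000
rs2005	A	G	0.55	-0.00952811	0.01	0.3407	460000
rs2006	C	A	0.29	0.000411746	0.01	0.9672	460000
rs2007	A	T	0.5	0.00366937	0.01	0.7137	460000
rs2008	G	C	0.73	-0.000859831	0.01	0.9315	460000
rs3001	T	C	0.45	-0.00436183	0.01	0.6627	460000
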