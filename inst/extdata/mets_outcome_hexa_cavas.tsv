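snp_id	effect_allele	other_allele	eaf	or	ci_low	ci_high	p	n	trait
rs12567136	A	G	0.85	0.998	0.976	1.020	0.867	5509	outcome
rs1801133	G	A	0.66	0.949	0.850	1.059	0.354	5509	outcome
rs2336377	G	A	0.80	1.005	0.988	1.022	0.577	5509	outcome
rs1624230	C	T	0.55	0.998	0.981	1.014	0.774	5509	outcome
rs1836883	T	C	0.35	0.983	0.967	0.998	0.031	5509	outcome
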