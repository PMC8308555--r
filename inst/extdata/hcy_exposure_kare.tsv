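snp_id	chr	gene	effect_allele	other_allele	eaf	beta	se	p	n	trait
rs12567136	1	CLCN6	A	G	0.85	-0.058	0.008	3.23e-10	5902	exposure
rs1801133	1	MTHFR	G	A	0.66	-0.039	0.005	2.74e-17	5902	exposure
rs2336377	1	LOC390997	G	A	0.80	-0.045	0.008	1.74e-8	5902	exposure
rs1624230	3	KNG1	C	T	0.55	-0.027	0.005	3.81e-8	5902	exposure
rs1836883	11	NOX4	T	C	0.35	0.029	0.005	9.55e-10	5902	exposure
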