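snp	chr	pos	gene	ea	oa	eaf	beta	se	pval	n
rs1121980	16	NA	FTO	A	G	0.432	0.005	0.007	4.5e-01	NA
rs1260326	2	NA	GCKR	C	T	0.607	0.048	0.007	4.3e-13	NA
rs13389219	2	NA	COBLL1	T	C	0.394	0.053	0.007	1.1e-13	NA
rs2340550	19	NA	ACTL9	G	A	0.685	-0.016	0.007	2.6e-02	NA
rs3799260	6	NA	KLHL31	T	C	0.818	-0.038	0.008	3.8e-06	NA
rs62621812	7	NA	ZNF800	A	G	0.031	-0.127	0.018	2.8e-12	NA
rs791600	7	NA	LEP	A	G	0.411	-0.063	0.007	5.4e-19	NA
rs900399	3	NA	CCNL1	G	A	0.396	-0.040	0.007	9.2e-09	NA
rs972283	7	NA	KLF14	G	A	0.521	-0.056	0.006	3.8e-18	NA
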