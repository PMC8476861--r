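snp	chr	pos	gene	ea	oa	eaf	beta	se	pval	n
rs10487505	7	128220110	LEP	G	C	0.50	0.023	0.005	9.0e-06	NA
rs6071166	20	NA	SLC32A1	C	A	0.37	0.027	0.006	6.6e-07	NA
rs780093	2	NA	GCKR	C	T	0.61	0.032	0.005	2.3e-10	NA
rs8043757	16	NA	FTO	T	A	0.40	0.030	0.005	1.1e-09	NA
rs900400	3	NA	CCNL1	T	C	0.60	0.030	0.005	5.6e-09	NA
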