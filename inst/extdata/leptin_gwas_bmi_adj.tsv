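snp	chr	pos	gene	ea	oa	eaf	beta	se	pval	n
rs10487505	7	128220110	LEP	G	C	0.50	0.029	0.004	2.0e-12	NA
rs6071166	20	NA	SLC32A1	C	A	0.37	0.024	0.004	1.8e-08	NA
rs780093	2	NA	GCKR	C	T	0.61	0.024	0.004	3.8e-10	NA
rs8043757	16	NA	FTO	T	A	0.40	0.001	0.004	8.4e-01	NA
rs900400	3	NA	CCNL1	T	C	0.60	0.021	0.004	1.2e-07	NA
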