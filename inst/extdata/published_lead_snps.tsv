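CHR	RSID	A1	A2	GENE	BETA_SCZ	SE_SCZ	P_SCZ	BETA_PTSD	SE_PTSD	P_PTSD	Z_DIFF	P_DIFF
17	rs62062288	A	G	MAPT	-0.068	0.011	1.65E-09	0.023	0.006	7.14E-05	-5.46	4.87E-08
12	rs11057189	T	G	MPHOSPH9	0.073	0.010	5.67E-14	-0.019	0.005	4.30E-04	6.33	2.42E-10
7	rs58120505	T	C	MAD1L1	0.090	0.009	2.24E-24	-0.013	0.004	1.70E-03	7.99	1.30E-15
7	rs12536395	A	G	IMMP2L	-0.063	0.009	1.13E-11	0.013	0.005	3.49E-03	-5.58	2.40E-08
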