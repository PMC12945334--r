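CHR	RSID	A1	A2	Z	P
17	rs62062288	A	G	5.631	1.79E-08
12	rs11057189	T	G	-1.675	0.09403
7	rs58120505	T	C	-3.224	0.001264
7	rs12536395	A	G	1.557	0.1195
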