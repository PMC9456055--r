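chrom	pos	rsid	gene	ref	alt	alt_freq	n_hap
1	161514542	rs396991	FCGR3A	A	C	0.528	3154
16	31104509	rs8050894	VKORC1	C	G	0.523	3154
19	15990431	rs2108622	CYP4F2	C	T	0.415	3154
16	31107689	rs9923231	VKORC1	C	T	0.510	3154
16	31104878	rs9934438	VKORC1	G	A	0.510	3154
6	39325078	rs20455	KIF6	A	G	0.463	3154
1	11856378	rs1801133	MTHFR	G	A	0.424	3154
16	31105554	rs2884737	VKORC1	A	C	0.353	3154
1	97981395	rs1801159	DPYD	T	C	0.252	3154
1	98348885	rs1801265	DPYD	A	G	0.159	3154
21	46957794	rs1051266	SLC19A1	T	C	0.511	3154
6	31543031	rs1800629	TNF	G	A	0.050	3154
16	31103796	rs2359612	VKORC1	A	G	0.490	3154
1	207753621	rs2274567	CR1	A	G	0.608	3154
6	31093482	rs3131003	PSORS1C1	G	A	0.739	3154
6	31093587	rs3815087	PSORS1C1	G	A	0.507	3154
12	13953118	rs2058878	GRIN2B	G	A	0.602	3154
12	85243681	rs6539870	IL1B	A	G	0.486	3154
3	45732515	rs2742421	SACM1L	T	G	0.687	3154
6	31603770	rs11229	PRRC2A	A	G	0.435	3154
15	30193316	rs813676	TJP1	T	C	0.761	3154
6	31107361	rs2233945	PSORS1C1	C	A	0.417	3154
6	31604591	rs10885	PRRC2A	C	T	0.436	3154
6	31018546	rs2523864	HCG22	C	T	0.679	3154
19	15959200	rs2189784	CYP4F2	G	A	0.667	3154
6	31022113	rs3873352	HCG22	A	G	0.336	3154
6	43737794	rs13207351	VEGFA	A	G	0.611	3154
3	151090996	rs9859552	P2RY12	G	T	0.338	3154
6	31543101	rs361525	TNF	G	A	0.292	3154
6	31542308	rs1799964	TNF	T	C	0.447	3154
6	78173281	rs130058	HTR1B	T	A	0.414	3154
5	158750769	rs3213094	IL12B	C	T	0.427	3154
7	86331756	rs2189814	GRM3	T	C	0.375	3154
10	32202069	rs2799018	ARHGAP12	C	T	0.611	3154
10	92619161	rs7905446	HTR7	T	G	0.480	3154
6	33047612	rs3097671	HLA-DPB1	T	C	0.366	3154
1	29161999	rs2236855	OPRD1	G	A	0.386	3154
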