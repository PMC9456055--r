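annotation_id	rsid	gene	evidence_level	phenotype_category	drugs	pediatric
900000001	rs2274567	CR1	3	Efficacy	hydroxychloroquine	0
900000002	rs3131003	PSORS1C1	4	Toxicity	allopurinol	0
900000003	rs3815087	PSORS1C1	3	Toxicity	allopurinol	0
900000004	rs2058878	GRIN2B	3	Efficacy	memantine	0
900000005	rs6539870	IL1B	3	Efficacy	anakinra	0
900000006	rs2742421	SACM1L	3	Other	methadone	0
900000007	rs11229	PRRC2A	3	Toxicity	aspirin	0
900000008	rs813676	TJP1	3	Efficacy	metformin	0
900000009	rs2233945	PSORS1C1	3	Efficacy	etanercept	0
900000010	rs10885	PRRC2A	3	Toxicity	aspirin	0
900000011	rs2523864	HCG22	3	Toxicity	carbamazepine	0
900000012	rs2189784	CYP4F2	3	Dosage	warfarin	0
900000013	rs3873352	HCG22	3	Toxicity	carbamazepine	0
900000014	rs13207351	VEGFA	3	Efficacy	bevacizumab	0
900000015	rs9859552	P2RY12	3	Efficacy	clopidogrel	0
900000016	rs361525	TNF	3	Efficacy	etanercept	0
900000017	rs1799964	TNF	3	Efficacy	infliximab	0
900000018	rs130058	HTR1B	3	Efficacy	sumatriptan	0
900000019	rs3213094	IL12B	3	Efficacy	ustekinumab	0
900000020	rs2189814	GRM3	3	Efficacy	clozapine	0
900000021	rs2799018	ARHGAP12	3	Other	warfarin	0
900000022	rs7905446	HTR7	3	Efficacy	risperidone	0
900000023	rs3097671	HLA-DPB1	3	Toxicity	aspirin	1
900000024	rs2236855	OPRD1	3	Efficacy	naltrexone	0
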