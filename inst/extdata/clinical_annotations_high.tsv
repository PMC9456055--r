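annotation_id	rsid	gene	evidence_level	phenotype_category	drugs	pediatric
1184661194	rs2108622	CYP4F2	2A	Dosage	acenocoumarol	0
981204044	rs9923231	VKORC1	1A	Dosage	acenocoumarol	0
1183704228	rs9934438	VKORC1	2A	Dosage	acenocoumarol	0
1451237940	rs9923231	VKORC1	1A	Dosage	phenprocoumon	1
1451244040	rs9934438	VKORC1	2A	Dosage	phenprocoumon	1
655385400	rs2108622	CYP4F2	1A	Dosage	warfarin	1
982035703	rs2884737	VKORC1	2A	Dosage	warfarin	0
655385392	rs9934438	VKORC1	1B	Dosage	warfarin	1
655385028	rs8050894	VKORC1	1B	Dosage	warfarin	0
655385012	rs9923231	VKORC1	1A	Dosage	warfarin	1
655385024	rs2359612	VKORC1	1B	Dosage	warfarin	0
655384799	rs1800629	TNF	2B	Efficacy	etanercept	0
1451245360	rs1051266	SLC19A1	2A	Efficacy	methotrexate	0
655384621	rs20455	KIF6	2B	Efficacy	pravastatin	0
1444608384	rs396991	FCGR3A	2B	Efficacy	rituximab	0
1447672998	rs9923231	VKORC1	2A	Efficacy	warfarin	1
1447673015	rs9923231	VKORC1	2A	Efficacy	warfarin	1
1451286320	rs1801159	DPYD	1A	Toxicity	capecitabine	0
1451287240	rs1801265	DPYD	1A	Toxicity	capecitabine	0
981201981	rs1801265	DPYD	1A	Toxicity	fluorouracil	1
981201962	rs1801159	DPYD	1A	Toxicity	fluorouracil	0
827848365	rs1801133	MTHFR	2A	Toxicity	methotrexate	1
655385307	rs1801133	MTHFR	2A	Toxicity	methotrexate	1
1451243676	rs9923231	VKORC1	2A	Toxicity	phenprocoumon	0
1449269910	rs9923231	VKORC1	2A	Toxicity	warfarin	1
1447673005	rs9923231	VKORC1	1B	Toxicity	warfarin	1
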