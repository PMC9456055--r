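gene	allele1	allele2	phenotype
CFTR	*1	*1	Ivacaftor irrelevant
CFTR	*1	F508del	Ivacaftor irrelevant
CFTR	F508del	F508del	Ivacaftor non-responsive
CFTR	*1	G551D	Ivacaftor responsive
CFTR	G551D	G551D	Ivacaftor responsive
CFTR	F508del	G551D	Ivacaftor responsive
CYP2B6	*1	*1	Normal Metabolizer
CYP2B6	*1	*6	Intermediate Metabolizer
CYP2B6	*6	*6	Poor Metabolizer
CYP2B6	*1	*4	Rapid Metabolizer
CYP2B6	*4	*4	Rapid Metabolizer
CYP2B6	*4	*6	Intermediate Metabolizer
CYP2C19	*1	*1	Normal Metabolizer
CYP2C19	*1	*2	Intermediate Metabolizer
CYP2C19	*2	*2	Poor Metabolizer
CYP2C19	*1	*17	Rapid Metabolizer
CYP2C19	*17	*17	Ultrarapid Metabolizer
CYP2C19	*2	*17	Intermediate Metabolizer
CYP2C9	*1	*1	Normal Metabolizer
CYP2C9	*1	*2	Intermediate Metabolizer
CYP2C9	*1	*3	Intermediate Metabolizer
CYP2C9	*2	*2	Poor Metabolizer
CYP2C9	*2	*3	Poor Metabolizer
CYP2C9	*3	*3	Poor Metabolizer
CYP2D6	*1	*1	Normal Metabolizer
CYP2D6	*1	*4	Indeterminate
CYP2D6	*4	*4	Indeterminate
CYP3A5	*1	*1	Normal Metabolizer
CYP3A5	*1	*3	Intermediate Metabolizer
CYP3A5	*3	*3	Poor Metabolizer
CYP4F2	*1	*1	Normal dose phenotype
CYP4F2	*1	*3	Increased dose phenotype
CYP4F2	*3	*3	Increased dose phenotype
DPYD	*1	*1	Normal Metabolizer
DPYD	*1	*2A	Intermediate Metabolizer
DPYD	*2A	*2A	Poor Metabolizer
IFNL3	*1	*1	Favorable response genotype
IFNL3	*1	*2	Unfavorable response genotype
IFNL3	*2	*2	Unfavorable response genotype
NUDT15	*1	*1	Normal Metabolizer
NUDT15	*1	*3	Intermediate Metabolizer
NUDT15	*3	*3	Poor Metabolizer
SLCO1B1	*1	*1	Normal Function
SLCO1B1	*1	*5	Decreased Function
SLCO1B1	*5	*5	Poor Function
SLCO1B1	*1	*14	Possible increased function
SLCO1B1	*14	*14	Possible increased function
SLCO1B1	*5	*14	Indeterminate
TPMT	*1	*1	Normal Function
TPMT	*1	*2	Intermediate Function
TPMT	*1	*3A	Intermediate Function
TPMT	*2	*2	Poor Function
TPMT	*2	*3A	Poor Function
TPMT	*3A	*3A	Poor Function
UGT1A1	*1	*1	Normal Metabolizer
UGT1A1	*1	*28	Intermediate Metabolizer
UGT1A1	*28	*28	Poor Metabolizer
VKORC1	-1639G	-1639G	Normal warfarin dose
VKORC1	-1639G	-1639A	Possibly decreased warfarin dose
VKORC1	-1639A	-1639A	Decreased warfarin dose
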