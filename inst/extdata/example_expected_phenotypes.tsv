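sample_id	gene	diplotype	phenotype
EX001	CYP2B6	*1/*1	NM
EX001	CYP2C19	*1/*1	NM
EX001	CYP2D6	*1/*1	NM
EX001	CYP3A4	*1/*1	NM
EX002	CYP2B6	*1/*1	NM
EX002	CYP2C19	*1/*17	RM
EX002	CYP2D6	*4/*4	PM
EX002	CYP3A4	*1/*1	NM
EX003	CYP2B6	*6/*6	PM
EX003	CYP2C19	*1/*1	NM
EX003	CYP2D6	*5/*41	IM
EX003	CYP3A4	*1/*1	NM
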