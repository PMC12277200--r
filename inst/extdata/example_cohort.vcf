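##fileformat=VCFv4.2
##source=pgxCohort worked example (synthetic build synth1)
##contig=<ID=CYP2D6>
##contig=<ID=CYP2C19>
##contig=<ID=CYP2B6>
##contig=<ID=CYP3A4>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	EX001	EX002	EX003
CYP2D6	270	.	G	A	.	PASS	.	GT	0/0	0/0	1/1
CYP2D6	304	.	A	G	.	PASS	.	GT	0/0	1/1	0/0
CYP2C19	100	.	A	G	.	PASS	.	GT	0/0	0/1	0/0
CYP2B6	151	.	T	C	.	PASS	.	GT	0/0	0/0	1/1
CYP2B6	168	.	A	G	.	PASS	.	GT	0/0	0/0	1/1
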