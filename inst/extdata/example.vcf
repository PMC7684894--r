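##fileformat=VCFv4.2
##source=hand-written-example
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA1	NA2	NA3
1	101	rs1	A	G	.	PASS	.	GT	0/0	0/1	1/1
1	205	rs2	T	C	.	PASS	.	GT	0|1	./.	1|1
2	77	rs3	G	A	.	PASS	.	GT	1/1	0/0	0/1
2	300	rs4	C	T	.	PASS	.	GT	0/0	0/0	0/1
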