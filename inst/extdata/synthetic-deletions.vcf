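##fileformat=VCFv4.2
##contig=<ID=chr1,length=4440>
##INFO=<ID=CLNSIG,Number=.,Type=String,Description="Clinical significance">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	200	planted_chr1_200	CTAG	C	.	.	CLNSIG=Pathogenic
chr1	600	planted_chr1_600	GTCGC	G	.	.	.
chr1	1000	planted_chr1_1000	AGAGCCG	A	.	.	CLNSIG=Likely_pathogenic
chr1	1405	planted_chr1_1400	CAACGTC	C	.	.	CLNSIG=Benign
chr1	1800	planted_chr1_1800	ATGCAGGATCC	A	.	.	.
chr1	2200	planted_chr1_2200	GGCGTACAACTGCTGTGGT	G	.	.	CLNSIG=Uncertain_significance
chr1	2600	planted_chr1_2600	GCCTCCGA	G	.	.	CLNSIG=Pathogenic|Likely_pathogenic
chr1	3000	planted_chr1_3000	TTGCC	T	.	.	.
chr1	3400	planted_chr1_3400	TGAAAA	T	.	.	.
chr1	3803	planted_chr1_3800	GTTTG	G	.	.	CLNSIG=Benign
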