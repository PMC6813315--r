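##gff-version 3
chr1	delmh	gene	1	2400	.	+	.	ID=geneA
chr1	delmh	exon	100	700	.	+	.	ID=geneA.e1;Parent=geneA
chr1	delmh	five_prime_UTR	100	180	.	+	.	ID=geneA.u1;Parent=geneA
chr1	delmh	CDS	181	700	.	+	0	ID=geneA.c1;Parent=geneA
chr1	delmh	exon	900	1500	.	+	.	ID=geneA.e2;Parent=geneA
chr1	delmh	CDS	900	1500	.	+	0	ID=geneA.c2;Parent=geneA
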