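#!toy annotation for examples
chr1	example	exon	11	40	.	+	.	gene_id "g1"; transcript_id "g1.t1"; transcript_biotype "protein_coding";
chr1	example	exon	61	90	.	+	.	gene_id "g1"; transcript_id "g1.t1"; transcript_biotype "protein_coding";
chr1	example	exon	11	40	.	+	.	gene_id "g1"; transcript_id "g1.t2"; transcript_biotype "protein_coding";
chr1	example	exon	121	150	.	+	.	gene_id "g1"; transcript_id "g1.t2"; transcript_biotype "protein_coding";
chr1	example	exon	201	260	.	-	.	gene_id "g2"; transcript_id "g2.t1"; transcript_biotype "lncRNA";
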