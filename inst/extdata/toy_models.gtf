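chrT	toy	gene	101	600	.	+	.	gene_id "GA"; gene_name "GENEA";
chrT	toy	transcript	101	600	.	+	.	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	exon	101	200	.	+	.	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	exon	301	400	.	+	.	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	exon	501	600	.	+	.	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	CDS	151	200	.	+	0	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	CDS	301	400	.	+	1	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	CDS	501	560	.	+	0	gene_id "GA"; transcript_id "tA1"; gene_name "GENEA";
chrT	toy	transcript	101	600	.	+	.	gene_id "GA"; transcript_id "tA2"; gene_name "GENEA";
chrT	toy	exon	101	200	.	+	.	gene_id "GA"; transcript_id "tA2"; gene_name "GENEA";
chrT	toy	exon	501	600	.	+	.	gene_id "GA"; transcript_id "tA2"; gene_name "GENEA";
chrT	toy	gene	801	1100	.	+	.	gene_id "GB"; gene_name "GENEB";
chrT	toy	transcript	801	1100	.	+	.	gene_id "GB"; transcript_id "tB1"; gene_name "GENEB";
chrT	toy	exon	801	900	.	+	.	gene_id "GB"; transcript_id "tB1"; gene_name "GENEB";
chrT	toy	exon	1001	1100	.	+	.	gene_id "GB"; transcript_id "tB1"; gene_name "GENEB";
chrT	toy	CDS	841	900	.	+	0	gene_id "GB"; transcript_id "tB1"; gene_name "GENEB";
chrT	toy	CDS	1001	1090	.	+	0	gene_id "GB"; transcript_id "tB1"; gene_name "GENEB";
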