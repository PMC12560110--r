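##gff-version 3
p_plasmid	symcurate	CDS	100	1100	.	+	.	product=ParA family plasmid partitioning protein
p_plasmid	symcurate	CDS	1200	2100	.	+	.	product=ParB family partition protein
p_plasmid	symcurate	CDS	2200	2900	.	+	.	product=hypothetical protein
p_plasmid	symcurate	CDS	3000	3700	.	+	.	product=hypothetical protein
p_plasmid	symcurate	CDS	3800	4500	.	+	.	product=hypothetical protein
p_plasmid	symcurate	CDS	4600	5300	.	+	.	product=hypothetical protein
p_plasmid	symcurate	CDS	5400	5900	.	+	.	product=IS110 family transposase
p_chrom	symcurate	CDS	100	1100	.	+	.	product=30S ribosomal protein S3
p_chrom	symcurate	CDS	1200	2200	.	+	.	product=DNA gyrase subunit B
p_chrom	symcurate	CDS	2300	3300	.	+	.	product=elongation factor Tu
p_chrom	symcurate	CDS	3400	4400	.	+	.	product=hypothetical protein
p_chrom	symcurate	CDS	4500	5500	.	+	.	product=hypothetical protein
p_small	symcurate	CDS	100	1100	.	+	.	product=ParA family plasmid partitioning protein
p_small	symcurate	CDS	1200	1900	.	+	.	product=hypothetical protein
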