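sample	cnv1_diploid	cnv2_diploid	srcr_diploid_cn	secretor	fut2_genotype	isoform	bands	smutans_binding
1	2	7	27	+	G/A	III	389	+
2	2	4	24	-	A/A	I	345	-
3	2	2	22	+	G/A	I	345	-
4	2	6	26	+	G/A	II	375	+
5	2	4	24	+	G/A	II	375	+
6	1	4	20	-	A/A	IV	287,345	-
7	2	5	25	+	G/A	II	375	+
8	2	9	29	+	G/A	III	389	+
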