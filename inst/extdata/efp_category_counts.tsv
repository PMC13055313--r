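# Published functional-category counts of differentially expressed genes
# (RNA-seq, |log2FC| > 1) and proteins (iTRAQ, >1.5 / <0.7) in a
# B. subtilis efp deletion mutant versus wild type. Percent columns are the
# published per-category shares of each layer's summed Total column.
category	rna_up	rna_down	rna_total	rna_pct	protein_up	protein_down	protein_total	protein_pct
Cell envelope and cell wall synthesis	27	35	62	6	0	6	6	3
Transporters	54	39	94	8	1	8	9	4
Homeostasis	4	4	8	0.7	0	6	6	3
Electron transfer and ATP synthesis	19	10	29	3	3	16	19	9
Carbon metabolism	8	22	30	3	3	3	6	3
Amino acids and nitrogen metabolism	29	31	60	5	5	5	10	5
Lipid metabolism	17	7	24	2	2	2	4	2
Nucleotide metabolism	4	7	11	1	0	0	0	0
Additional metabolism	14	32	46	4	2	14	16	7
Detoxification	0	3	3	0.3	0	0	0	0
Genetics	16	9	25	2	1	10	11	6
RNA synthesis and degradation	7	4	11	1	0	1	1	0.5
Protein synthesis, modification, and degradation	52	55	107	10	16	11	27	12
Regulation of gene expression	37	22	58	5	4	8	12	6
Exponential and post-exponential lifestyles	8	12	20	2	1	9	10	5
Sporulation	13	251	264	24	1	18	19	9
Coping with stress	34	21	55	5	0	9	9	4
Miscellaneous lifestyles	2	0	2	0.2	0	0	0	0
Prophage and mobile genetic elements	10	5	15	1	0	6	6	3
Unknown or poorly characterized proteins	123	62	185	17	17	31	48	22
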