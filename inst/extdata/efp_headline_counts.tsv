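# Published dataset-level counts for the same efp-mutant experiment:
# detected features per layer, differential calls, and the nested candidate
# funnel (protein-down -> down with XPPX motif -> mRNA-driven -> direct
# EF-P-dependent translational candidates -> stall-atlas supported).
quantity	value
rna_detected	4457
rna_up	478
rna_down	633
rna_down_sporulation	251
protein_detected	2187
protein_up	231
protein_down	432
protein_down_with_xppx	114
protein_down_mrna_driven	109
efp_direct_candidates	84
efp_direct_stall_supported	19
genome_xppx_genes	927
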