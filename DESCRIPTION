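Package: efpTargets
Title: Identify EF-P-Dependent Translational Targets from Paired Transcriptome and Proteome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the regulatory mode of each protein in an
    elongation-factor-P (efp) mutant of Bacillus subtilis by integrating
    XPPX diproline stall-motif scanning of the proteome with dual-threshold
    differential calls on paired RNA-seq and iTRAQ abundance tables.
    Proteins that decrease at the protein level, carry an XPPX motif, and
    show no matching mRNA decrease are flagged as direct EF-P-dependent
    translational targets; the nested candidate counts are reported as a
    funnel together with a functional-category summary table. A seeded
    synthetic-data generator plants XPPX-dependent translational
    attenuation, negative-binomial count noise, and iTRAQ dynamic-range
    compression so that every pipeline stage can be tested against known
    ground truth without the original sequencing and mass-spectrometry
    deposits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
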