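# Accessors for the published efp-mutant reference counts shipped with the
# package. These are desk-check inputs (per-category and dataset-level
# counts from a B. subtilis efp-mutant RNA-seq/iTRAQ comparison), used to
# validate the percentage arithmetic of the category summary; the
# underlying per-gene data live in public repositories and are not needed
# by the package.

#' Published per-category differential counts for the efp mutant
#'
#' Per-category Increase/Decrease/Total counts and published percentage
#' shares for both omics layers of a *B. subtilis* efp-mutant experiment
#' (RNA-seq DEGs at |log2FC| > 1; iTRAQ proteins at >1.5 / <0.7).
#'
#' @return Data frame with columns `category`, `rna_up`, `rna_down`,
#'   `rna_total`, `rna_pct`, `protein_up`, `protein_down`, `protein_total`,
#'   `protein_pct`.
#' @export
efp_category_counts <- function() {
  utils::read.delim(system.file("extdata", "efp_category_counts.tsv",
                                package = "efpTargets", mustWork = TRUE),
                    comment.char = "#", check.names = TRUE)
}

#' Published dataset-level counts for the efp mutant
#'
#' Detected-feature counts, differential-call counts, and the nested
#' candidate-funnel counts of the same experiment, as a named numeric
#' vector (e.g. `rna_down`, `protein_down_with_xppx`,
#' `efp_direct_candidates`).
#'
#' @return Named numeric vector.
#' @export
efp_headline_counts <- function() {
  df <- utils::read.delim(system.file("extdata", "efp_headline_counts.tsv",
                                      package = "efpTargets",
                                      mustWork = TRUE),
                          comment.char = "#")
  stats::setNames(as.numeric(df$value), df$quantity)
}
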