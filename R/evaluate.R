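# Convenience drivers for running the classification on a simulated
# dataset and scoring it against the planted truth.

#' Classify a simulated dataset
#'
#' Runs the in-memory analysis chain on a [simulate_dataset()] result:
#' motif scan, CPM normalization, fold-change calls on both layers,
#' per-protein classification, and the candidate funnel.
#'
#' @param sim A `sim_dataset`.
#' @param te_threshold,rna_up,rna_down,protein_up,protein_down,pseudocount
#'   Passed to [fold_change()] and [classify_proteins()] (log2-scale rna
#'   thresholds).
#' @return A list: `inventory`, `funnel`, `rna_fc`, `prot_fc`, `motifs`.
#' @export
classify_dataset <- function(sim, te_threshold = 0.7,
                             rna_up = 1, rna_down = -1,
                             protein_up = 1.5, protein_down = 0.7,
                             pseudocount = 0.5) {
  stopifnot(inherits(sim, "sim_dataset"))
  mt <- proteome_motif_table(sim$proteome)
  rna_fc <- fold_change(normalize_counts(sim$rna), pseudocount = pseudocount,
                        rna_up = rna_up, rna_down = rna_down)
  prot_fc <- fold_change(sim$protein, protein_up = protein_up,
                         protein_down = protein_down)
  inventory <- classify_proteins(prot_fc, rna_fc, mt$flags,
                                 te_threshold = te_threshold,
                                 rna_up = rna_up, rna_down = rna_down,
                                 protein_up = protein_up,
                                 protein_down = protein_down)
  list(inventory = inventory,
       funnel = build_funnel(inventory),
       rna_fc = rna_fc, prot_fc = prot_fc, motifs = mt)
}

#' Score direct-candidate calls against the planted truth
#'
#' Precision and recall of the `efp_direct_candidate` class against the
#' simulator's planted translational targets.
#'
#' @param inventory Inventory data frame from [classify_proteins()].
#' @param truth Truth data frame from [generate_truth()] (matched by gene
#'   name to `protein_id`).
#' @return Named numeric vector: `tp`, `fp`, `fn`, `precision`, `recall`.
#'   Precision is `NA` when nothing was called; recall is `NA` when nothing
#'   was planted.
#' @export
recovery_metrics <- function(inventory, truth) {
  called <- inventory$mode == "efp_direct_candidate"
  planted <- truth$translational_target[match(inventory$protein_id,
                                              truth$gene)]
  stopifnot(!anyNA(planted))
  tp <- sum(called & planted)
  fp <- sum(called & !planted)
  fn <- sum(!called & planted)
  c(tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
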