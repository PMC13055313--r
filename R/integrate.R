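# Integration of motif flags with paired transcript/protein fold changes:
# per-protein regulatory-mode classification, the candidate funnel, and
# cross-referencing against a ribosome-stalling atlas.

REG_MODES <- c("efp_direct_candidate", "transcriptional", "secondary",
               "translational_attenuation_masked", "unclassified")

#' Classify one protein's regulatory mode
#'
#' The classifier separates translational from transcriptional regulation by
#' asking whether a protein-level decrease is explained by an mRNA decrease.
#' Rules are applied in order:
#'
#' 1. protein down AND rna down -> `transcriptional` (the mRNA decrease
#'    explains the protein decrease);
#' 2. protein down AND XPPX motif AND rna not down ->
#'    `efp_direct_candidate` (less protein made per transcript at a
#'    stall-prone motif: the direct EF-P target class);
#' 3. protein down, no motif, rna not down -> `secondary`;
#' 4. protein up AND XPPX motif AND translational-efficiency ratio below
#'    `te_threshold` -> `translational_attenuation_masked` (transcriptional
#'    induction masks a per-mRNA decrease);
#' 5. otherwise `unclassified`.
#'
#' The translational-efficiency (TE) ratio is the protein mutant/wild ratio
#' divided by the rna mutant/wild ratio; TE < 1 means less protein made per
#' transcript in the mutant. The masked-class cutoff reuses the protein
#' down-threshold 0.7 by default.
#'
#' Proteins with no transcript record are treated as rna-unchanged (rna
#' ratio 1) and flagged `no_rna_evidence = TRUE`; absence of mRNA evidence
#' does not exclude a protein from the direct-candidate class, which only
#' requires that no mRNA decrease was demonstrated.
#'
#' @param prot_ratio Protein mutant/wild ratio (positive scalar).
#' @param protein_id Identifier copied into the result.
#' @param rna_log2fc Transcript log2 fold change, or `NA` if the gene was
#'   not detected in the transcriptome.
#' @param has_xppx Logical: does the protein carry >= 1 XPPX motif?
#' @param te_threshold TE-ratio cutoff for the masked class (default 0.7).
#' @param rna_up,rna_down Log2 thresholds defining the transcript call.
#' @param protein_up,protein_down Linear thresholds defining the protein call.
#' @return A one-row data frame: `protein_id`, `rna_call`, `protein_call`,
#'   `has_xppx`, `te_ratio`, `mode`, `no_rna_evidence`, `stall_support`.
#' @examples
#' classify_protein(0.5, 0.0, TRUE)   # efp_direct_candidate
#' classify_protein(0.5, -2.0, TRUE)  # transcriptional
#' classify_protein(2.0, 2.5, TRUE)   # translational_attenuation_masked
#' @export
classify_protein <- function(prot_ratio, rna_log2fc, has_xppx,
                             protein_id = "protein",
                             te_threshold = 0.7,
                             rna_up = 1, rna_down = -1,
                             protein_up = 1.5, protein_down = 0.7) {
  stopifnot(length(prot_ratio) == 1L, prot_ratio > 0,
            length(rna_log2fc) == 1L, is.logical(has_xppx))
  no_rna <- is.na(rna_log2fc)
  if (no_rna) rna_log2fc <- 0
  rna_call <- call_transcript(rna_log2fc, up = rna_up, down = rna_down)
  protein_call <- call_protein(prot_ratio, up = protein_up,
                               down = protein_down)
  te_ratio <- prot_ratio / 2^rna_log2fc
  mode <-
    if (protein_call == "down" && rna_call == "down") {
      "transcriptional"
    } else if (protein_call == "down" && has_xppx) {
      "efp_direct_candidate"
    } else if (protein_call == "down") {
      "secondary"
    } else if (protein_call == "up" && has_xppx && te_ratio < te_threshold) {
      "translational_attenuation_masked"
    } else {
      "unclassified"
    }
  data.frame(protein_id = protein_id,
             rna_call = rna_call, protein_call = protein_call,
             has_xppx = has_xppx, te_ratio = te_ratio, mode = mode,
             no_rna_evidence = no_rna, stall_support = FALSE,
             stringsAsFactors = FALSE)
}

#' Classify every detected protein against the paired transcriptome
#'
#' Vectorized driver over [classify_protein()]'s rules. Every protein in
#' `prot_fc` must have a motif flag; transcript records are matched by
#' feature id and may be missing (see [classify_protein()]).
#'
#' @param prot_fc Protein-layer fold-change data frame (see [fold_change()]
#'   or [fold_change_from_ratio()]).
#' @param rna_fc Rna-layer fold-change data frame.
#' @param motif_flags Data frame `protein_id`, `has_xppx` (e.g. the `flags`
#'   element of [proteome_motif_table()]).
#' @inheritParams classify_protein
#' @return The per-protein inventory: one row per protein in `prot_fc`
#'   order, columns as in [classify_protein()].
#' @export
classify_proteins <- function(prot_fc, rna_fc, motif_flags,
                              te_threshold = 0.7,
                              rna_up = 1, rna_down = -1,
                              protein_up = 1.5, protein_down = 0.7) {
  stopifnot(is.data.frame(prot_fc), is.data.frame(motif_flags))
  ids <- prot_fc$feature_id
  fl <- motif_flags$has_xppx[match(ids, motif_flags$protein_id)]
  if (anyNA(fl)) {
    stop("no motif flag for protein(s): ",
         paste(utils::head(ids[is.na(fl)], 5L), collapse = ", "),
         call. = FALSE)
  }
  rl <- rna_fc$log2fc[match(ids, rna_fc$feature_id)]
  no_rna <- is.na(rl)
  rl[no_rna] <- 0
  rna_call <- call_transcript(rl, up = rna_up, down = rna_down)
  protein_call <- call_protein(prot_fc$ratio, up = protein_up,
                               down = protein_down)
  te_ratio <- prot_fc$ratio / 2^rl
  p_down <- protein_call == "down"
  r_down <- rna_call == "down"
  mode <- rep("unclassified", length(ids))
  mode[protein_call == "up" & fl & te_ratio < te_threshold] <-
    "translational_attenuation_masked"
  mode[p_down] <- "secondary"
  mode[p_down & fl & !r_down] <- "efp_direct_candidate"
  mode[p_down & r_down] <- "transcriptional"
  data.frame(protein_id = ids,
             rna_call = rna_call, protein_call = protein_call,
             has_xppx = fl, te_ratio = unname(te_ratio), mode = mode,
             no_rna_evidence = no_rna,
             stall_support = rep(FALSE, length(ids)),
             stringsAsFactors = FALSE)
}

#' Build the nested candidate funnel
#'
#' Counts the nested sets detected -> changed -> down -> down-with-XPPX ->
#' direct translational candidates, the report that summarizes how many
#' protein-level decreases are attributable to EF-P-dependent translation.
#'
#' @param calls Inventory data frame from [classify_proteins()].
#' @param n_detected_rna,n_detected_protein Number of features detected in
#'   each layer (defaults: rows carrying rna evidence / all rows).
#' @return A list of class `funnel_counts` with elements `n_detected_rna`,
#'   `n_detected_protein`, `n_rna_up`, `n_rna_down`, `n_protein_up`,
#'   `n_protein_down`, `n_down_with_xppx`, `n_down_mrna_driven`,
#'   `n_efp_direct`.
#' @export
build_funnel <- function(calls,
                         n_detected_rna = sum(!calls$no_rna_evidence),
                         n_detected_protein = nrow(calls)) {
  p_down <- calls$protein_call == "down"
  out <- list(
    n_detected_rna = as.integer(n_detected_rna),
    n_detected_protein = as.integer(n_detected_protein),
    n_rna_up = sum(calls$rna_call == "up"),
    n_rna_down = sum(calls$rna_call == "down"),
    n_protein_up = sum(calls$protein_call == "up"),
    n_protein_down = sum(p_down),
    n_down_with_xppx = sum(p_down & calls$has_xppx),
    n_down_mrna_driven = sum(p_down & calls$rna_call == "down"),
    n_efp_direct = sum(calls$mode == "efp_direct_candidate")
  )
  out <- lapply(out, as.integer)
  stopifnot(out$n_efp_direct <= out$n_down_with_xppx,
            out$n_down_with_xppx <= out$n_protein_down,
            out$n_down_mrna_driven <= out$n_protein_down)
  structure(out, class = "funnel_counts")
}

#' @export
print.funnel_counts <- function(x, ...) {
  cat("candidate funnel:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Write funnel counts as JSON
#'
#' @param funnel A `funnel_counts` object from [build_funnel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_funnel_json <- function(funnel, path) {
  jsonlite::write_json(unclass(funnel), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Cross-reference the inventory against a ribosome-stalling atlas
#'
#' A Ribo-seq stalling atlas lists (protein, position) sites of elevated
#' ribosome occupancy. A protein gains `stall_support = TRUE` iff the atlas
#' lists a position within `window` residues of any of its XPPX hits; the
#' default window of 1 residue absorbs the positional jitter of
#' ribosome-profiling assignments. Atlas entries for proteins absent from
#' the inventory raise a warning and are ignored.
#'
#' @param calls Inventory data frame from [classify_proteins()].
#' @param atlas Data frame with columns `protein_id`, `position`.
#' @param hits XPPX hits data frame (see [proteome_motif_table()]), or a
#'   `motif_table`.
#' @param window Nonnegative integer tolerance in residues (default 1).
#' @return `calls` with `stall_support` updated.
#' @export
annotate_stalling <- function(calls, atlas, hits, window = 1L) {
  stopifnot(window >= 0)
  if (inherits(hits, "motif_table")) hits <- hits$hits
  unknown <- setdiff(unique(atlas$protein_id), calls$protein_id)
  if (length(unknown) > 0L) {
    warning("atlas entries for unknown protein(s) ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    atlas <- atlas[!atlas$protein_id %in% unknown, , drop = FALSE]
  }
  supported <- vapply(calls$protein_id, function(id) {
    hp <- hits$position[hits$protein_id == id]
    ap <- atlas$position[atlas$protein_id == id]
    length(hp) > 0L && length(ap) > 0L &&
      any(abs(outer(hp, ap, "-")) <= window)
  }, logical(1))
  calls$stall_support <- unname(supported)
  calls
}
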