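# Abundance tables and dual-threshold fold-change calling.
#
# The two omics layers use the thresholds they were measured with:
# transcripts |log2FC| > 1 (i.e. > 2-fold or < 0.5-fold), proteins > 1.5-fold
# up or < 0.7-fold down. All inequalities are strict; values exactly on a
# threshold are called unchanged.

#' Construct an abundance table
#'
#' A light container for a feature-by-sample abundance matrix from a
#' two-condition (wild type vs mutant) design. Transcript tables hold
#' read counts; protein tables hold iTRAQ-style abundances (a pooled design
#' with one column per condition is fine).
#'
#' @param values Numeric matrix, features in rows (unique rownames required),
#'   samples in columns. No negative values.
#' @param condition Character vector, one of `"wild"`/`"mutant"` per column;
#'   each condition needs at least one replicate.
#' @param layer `"rna"` or `"protein"`.
#' @return An object of class `abundance_table` (list with `values`,
#'   `condition`, `layer`).
#' @export
abundance_table <- function(values, condition, layer = c("rna", "protein")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop("values must have feature ids as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (any(values < 0)) stop("abundances must be nonnegative", call. = FALSE)
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("one condition label per column required", call. = FALSE)
  }
  if (!all(condition %in% c("wild", "mutant"))) {
    stop("condition labels must be 'wild' or 'mutant'", call. = FALSE)
  }
  if (!all(c("wild", "mutant") %in% condition)) {
    stop("need at least one replicate per condition", call. = FALSE)
  }
  structure(list(values = values, condition = condition, layer = layer),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table [", x$layer, "]: ", nrow(x$values), " features, ",
      sum(x$condition == "wild"), " wild + ",
      sum(x$condition == "mutant"), " mutant replicates\n", sep = "")
  invisible(x)
}

#' Read an abundance table from TSV
#'
#' First column is the feature id; remaining columns are named
#' `<condition>_<replicate>`, e.g. `wild_1`, `mutant_2`.
#'
#' @param path Input TSV path.
#' @param layer `"rna"` or `"protein"`.
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path, layer = c("rna", "protein")) {
  layer <- match.arg(layer)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (ncol(df) < 3L) {
    stop(path, ": need a feature id column and >= 2 sample columns",
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- as.character(df[[1L]])
  cond <- sub("_[^_]*$", "", colnames(vals))
  abundance_table(vals, cond, layer)
}

#' Normalize transcript counts to counts-per-million
#'
#' Each replicate column is scaled so that it sums to one million. No
#' pseudocount is added here; [fold_change()] adds its pseudocount when
#' forming ratios.
#'
#' @param table An rna-layer [abundance_table()] of integer counts.
#' @return The table with CPM values.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$layer != "rna") {
    stop("normalize_counts applies to the rna layer", call. = FALSE)
  }
  v <- table$values
  if (any(v != round(v))) {
    stop("counts must be integers", call. = FALSE)
  }
  libsize <- colSums(v)
  if (any(libsize == 0)) {
    stop("replicate(s) with zero total count: ",
         paste(colnames(v)[libsize == 0], collapse = ", "), call. = FALSE)
  }
  table$values <- sweep(v, 2L, libsize, "/") * 1e6
  table
}

#' Call a transcript fold change
#'
#' Differentially expressed genes are those with |log2 fold change| > 1,
#' strictly: a log2 fold change of exactly 1 is unchanged.
#'
#' @param log2fc Numeric vector of log2(mutant/wild) values.
#' @param up,down Log2-scale thresholds (defaults 1 and -1).
#' @return Character vector: `"up"`, `"down"`, or `"unchanged"`.
#' @examples
#' call_transcript(c(1.2, 1, -3))  # up, unchanged, down
#' @export
call_transcript <- function(log2fc, up = 1, down = -1) {
  stopifnot(is.numeric(log2fc), all(is.finite(log2fc)), down < up)
  ifelse(log2fc > up, "up", ifelse(log2fc < down, "down", "unchanged"))
}

#' Call a protein fold change
#'
#' iTRAQ ratios are called with the asymmetric thresholds > 1.5 (up) and
#' < 0.7 (down), strictly: ratios exactly 1.5 or 0.7 are unchanged. The
#' asymmetry (0.7 != 1/1.5) reflects the compressed dynamic range of
#' reporter-ion ratios.
#'
#' @param ratio Positive numeric vector of mutant/wild protein ratios.
#' @param up,down Linear-scale thresholds (defaults 1.5 and 0.7).
#' @return Character vector: `"up"`, `"down"`, or `"unchanged"`.
#' @examples
#' call_protein(c(1.6, 0.7, 0.69))  # up, unchanged, down
#' @export
call_protein <- function(ratio, up = 1.5, down = 0.7) {
  stopifnot(is.numeric(ratio), all(is.finite(ratio)), all(ratio > 0),
            down < 1, up > 1)
  ifelse(ratio > up, "up", ifelse(ratio < down, "down", "unchanged"))
}

#' Per-feature fold changes with layer-appropriate calls
#'
#' The ratio is mean(mutant replicates) / mean(wild replicates). For the rna
#' layer a pseudocount is added to both means to stabilize ratios of
#' low-abundance genes (and guarantee a positive denominator); the table
#' should already be CPM-normalized (see [normalize_counts()]). Protein
#' tables are used as-is with no pseudocount.
#'
#' @param table An [abundance_table()].
#' @param pseudocount Added to each condition mean on the rna layer
#'   (default 0.5; 0 disables it, in which case zero wild-type means are an
#'   error; ignored for proteins).
#' @param rna_up,rna_down Log2 thresholds for the rna layer.
#' @param protein_up,protein_down Linear thresholds for the protein layer.
#' @return Data frame with columns `feature_id`, `ratio`, `log2fc`, `call`,
#'   `layer`.
#' @export
fold_change <- function(table, pseudocount = 0.5,
                        rna_up = 1, rna_down = -1,
                        protein_up = 1.5, protein_down = 0.7) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  mw <- rowMeans(v[, table$condition == "wild", drop = FALSE])
  mm <- rowMeans(v[, table$condition == "mutant", drop = FALSE])
  if (table$layer == "rna") {
    stopifnot(pseudocount >= 0)
    if (any(mw + pseudocount == 0)) {
      stop("zero wild-type mean with zero pseudocount for feature(s): ",
           paste(utils::head(rownames(v)[mw + pseudocount == 0], 5L),
                 collapse = ", "), call. = FALSE)
    }
    ratio <- (mm + pseudocount) / (mw + pseudocount)
    call <- call_transcript(log2(ratio), up = rna_up, down = rna_down)
  } else {
    if (any(mw == 0)) {
      stop("protein feature(s) with zero wild-type mean: ",
           paste(utils::head(rownames(v)[mw == 0], 5L), collapse = ", "),
           call. = FALSE)
    }
    ratio <- mm / mw
    call <- call_protein(ratio, up = protein_up, down = protein_down)
  }
  data.frame(feature_id = rownames(v),
             ratio = unname(ratio),
             log2fc = unname(log2(ratio)),
             call = unname(call),
             layer = rep(table$layer, nrow(v)),
             stringsAsFactors = FALSE)
}

#' Fold-change records from precomputed protein ratios
#'
#' iTRAQ reports are often delivered as one mutant/wild ratio per protein;
#' this wraps such a ratio column into the same record shape as
#' [fold_change()].
#'
#' @param feature_id Character vector of protein ids.
#' @param ratio Positive ratios, same length.
#' @param protein_up,protein_down Linear thresholds.
#' @return Data frame as from [fold_change()], with `layer = "protein"`.
#' @export
fold_change_from_ratio <- function(feature_id, ratio,
                                   protein_up = 1.5, protein_down = 0.7) {
  stopifnot(length(feature_id) == length(ratio))
  data.frame(feature_id = as.character(feature_id),
             ratio = as.numeric(ratio),
             log2fc = log2(as.numeric(ratio)),
             call = call_protein(ratio, up = protein_up, down = protein_down),
             layer = rep("protein", length(feature_id)),
             stringsAsFactors = FALSE)
}

#' Write fold-change records as TSV
#'
#' @param fc Data frame from [fold_change()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fold_change <- function(fc, path) {
  utils::write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
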