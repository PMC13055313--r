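# Functional-category summaries of differential calls, with the mixed
# integer / one-decimal percentage formatting used for per-category shares.

UNKNOWN_CATEGORY <- "Unknown or poorly characterized proteins"

#' Round a percentage for a category-share column
#'
#' Shares of at least 1% are rounded to the nearest integer; nonzero shares
#' below 1% are rounded to one decimal so that small categories are not
#' reported as 0. Rounding is half-away-from-zero (so 23.805 -> 24,
#' 0.27 -> 0.3), not banker's rounding.
#'
#' @param pct Numeric vector of exact percentages (0..100).
#' @return Numeric vector of rounded percentages.
#' @export
round_pct <- function(pct) {
  stopifnot(all(pct >= 0))
  ifelse(pct > 0 & pct < 1,
         floor(pct * 10 + 0.5) / 10,
         floor(pct + 0.5))
}

#' Recompute per-category percentage shares from totals
#'
#' The denominator is the sum of the supplied totals (the table's own Total
#' column), and each share is rounded with [round_pct()].
#'
#' @param totals Named numeric vector, or data frame with columns `category`
#'   and `n_total`, of nonnegative per-category totals.
#' @return Data frame `category`, `pct`.
#' @export
recompute_percentages <- function(totals) {
  if (is.data.frame(totals)) {
    cats <- as.character(totals$category)
    n <- as.numeric(totals$n_total)
  } else {
    cats <- names(totals)
    if (is.null(cats)) cats <- as.character(seq_along(totals))
    n <- as.numeric(totals)
  }
  stopifnot(all(n >= 0))
  if (sum(n) == 0) {
    stop("total count is zero; percentages undefined", call. = FALSE)
  }
  data.frame(category = cats, pct = round_pct(100 * n / sum(n)),
             stringsAsFactors = FALSE)
}

#' Read a feature-to-category map from TSV
#'
#' Two columns: feature_id, category. One category per feature.
#'
#' @param path Input TSV path.
#' @return Data frame `feature_id`, `category`.
#' @export
read_category_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  names(df)[1:2] <- c("feature_id", "category")
  if (anyDuplicated(df$feature_id)) {
    stop(path, ": one category per feature required", call. = FALSE)
  }
  df[, c("feature_id", "category")]
}

#' Summarize differential calls by functional category
#'
#' Counts up- and downregulated features per functional category (unchanged
#' features are excluded) and attaches each category's share of the summed
#' Total column. Features without a mapping fall into
#' `"Unknown or poorly characterized proteins"`. Row order is the category
#' order of `catmap` (first appearance), with the Unknown fallback last.
#'
#' @param calls Fold-change data frame (see [fold_change()]).
#' @param catmap Data frame `feature_id`, `category`, or `NULL` to place
#'   every feature in the Unknown category.
#' @return Data frame `category`, `n_up`, `n_down`, `n_total`, `pct`. Zero
#'   up/down calls yield a zero-row table.
#' @export
summarize_categories <- function(calls, catmap = NULL) {
  stopifnot(is.data.frame(calls))
  changed <- calls[calls$call %in% c("up", "down"), , drop = FALSE]
  if (is.null(catmap)) {
    catmap <- data.frame(feature_id = character(), category = character())
  }
  cat_of <- catmap$category[match(changed$feature_id, catmap$feature_id)]
  cat_of[is.na(cat_of)] <- UNKNOWN_CATEGORY
  cat_order <- unique(c(unique(catmap$category), UNKNOWN_CATEGORY))
  cat_order <- cat_order[cat_order %in% cat_of]
  if (nrow(changed) == 0L) {
    return(data.frame(category = character(), n_up = integer(),
                      n_down = integer(), n_total = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  n_up <- vapply(cat_order, function(cc) {
    sum(cat_of == cc & changed$call == "up")
  }, integer(1))
  n_down <- vapply(cat_order, function(cc) {
    sum(cat_of == cc & changed$call == "down")
  }, integer(1))
  n_total <- n_up + n_down
  out <- data.frame(category = cat_order, n_up = n_up, n_down = n_down,
                    n_total = n_total,
                    pct = round_pct(100 * n_total / sum(n_total)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Format a category-share percentage for printing
#'
#' Integer-valued shares print without a decimal point; sub-1% shares keep
#' their single decimal (`0.7`, not `0.70` or `1`).
#'
#' @param pct Numeric vector from [round_pct()].
#' @return Character vector.
#' @export
format_pct <- function(pct) {
  ifelse(pct == floor(pct), sprintf("%d", as.integer(pct)),
         sprintf("%.1f", pct))
}
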