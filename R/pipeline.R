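# End-to-end orchestration: simulate/load -> scan -> call -> integrate ->
# summarize, with reproducible outputs.

#' Pipeline configuration
#'
#' Either a simulation block (`sim`) or paths to real inputs (`fasta`,
#' `rna`, `protein`) must be supplied. Thresholds are given on the linear
#' scale and validated as down < 1 < up per layer.
#'
#' @param out_dir Output directory.
#' @param sim A [sim_config()], or `NULL` to read files.
#' @param fasta,rna,protein,catmap,atlas Input paths (amino-acid FASTA;
#'   count TSV; protein abundance or ratio TSV; optional feature-to-category
#'   TSV; optional stalling-atlas TSV with columns protein_id, position).
#' @param rna_up,rna_down Linear transcript thresholds (defaults 2, 0.5,
#'   i.e. |log2FC| > 1).
#' @param protein_up,protein_down Linear protein thresholds (defaults 1.5,
#'   0.7).
#' @param te_threshold TE-ratio cutoff for the masked class (default 0.7).
#' @param stall_window Atlas matching window in residues (default 1).
#' @param pseudocount RNA pseudocount (default 0.5).
#' @param seed Seed recorded in the run log; overrides `sim$seed` when
#'   simulating.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            fasta = NULL, rna = NULL, protein = NULL,
                            catmap = NULL, atlas = NULL,
                            rna_up = 2, rna_down = 0.5,
                            protein_up = 1.5, protein_down = 0.7,
                            te_threshold = 0.7, stall_window = 1L,
                            pseudocount = 0.5, seed = 1L) {
  if (!(rna_down < 1 && 1 < rna_up) || !(protein_down < 1 && 1 < protein_up)) {
    stop("config error: thresholds must satisfy down < 1 < up per layer",
         call. = FALSE)
  }
  if (te_threshold <= 0 || stall_window < 0 || pseudocount <= 0) {
    stop("config error: te_threshold and pseudocount must be positive, ",
         "stall_window nonnegative", call. = FALSE)
  }
  if (is.null(sim) && (is.null(fasta) || is.null(rna) || is.null(protein))) {
    stop("config error: supply a sim block or fasta+rna+protein paths",
         call. = FALSE)
  }
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, sim = sim, fasta = fasta, rna = rna,
                 protein = protein, catmap = catmap, atlas = atlas,
                 rna_up = rna_up, rna_down = rna_down,
                 protein_up = protein_up, protein_down = protein_down,
                 te_threshold = te_threshold,
                 stall_window = as.integer(stall_window),
                 pseudocount = pseudocount, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a protein table that may hold abundances or precomputed ratios
#'
#' A TSV whose second column is named `ratio` is taken as precomputed
#' mutant/wild ratios; otherwise columns must be `<condition>_<replicate>`
#' abundances.
#'
#' @param path Input TSV path.
#' @param protein_up,protein_down Linear thresholds for the call.
#' @return A protein fold-change data frame (see [fold_change()]).
#' @export
read_protein_table <- function(path, protein_up = 1.5, protein_down = 0.7) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  if (ncol(df) >= 2L && names(df)[2L] == "ratio") {
    fold_change_from_ratio(df[[1L]], df$ratio,
                           protein_up = protein_up,
                           protein_down = protein_down)
  } else {
    fold_change(read_abundance_tsv(path, layer = "protein"),
                protein_up = protein_up, protein_down = protein_down)
  }
}

write_tsv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

align_categories <- function(summary, categories) {
  miss <- setdiff(categories, summary$category)
  if (length(miss) > 0L) {
    summary <- rbind(summary,
                     data.frame(category = miss, n_up = 0L, n_down = 0L,
                                n_total = 0L, pct = 0,
                                stringsAsFactors = FALSE))
  }
  summary[match(categories, summary$category), , drop = FALSE]
}

#' Render a side-by-side category summary for both omics layers
#'
#' @param summary_rna,summary_protein Data frames from
#'   [summarize_categories()]; they must cover the same set of categories
#'   (pad with zero rows if needed).
#' @return Data frame with columns `category`, then
#'   `rna_up/rna_down/rna_total/rna_pct` and the protein counterparts, in
#'   `summary_rna` row order; percentages are formatted with [format_pct()].
#' @export
render_table1 <- function(summary_rna, summary_protein) {
  d <- c(setdiff(summary_rna$category, summary_protein$category),
         setdiff(summary_protein$category, summary_rna$category))
  if (length(d) > 0L) {
    stop("category universes differ: ", paste(unique(d), collapse = ", "),
         call. = FALSE)
  }
  sp <- summary_protein[match(summary_rna$category,
                              summary_protein$category), , drop = FALSE]
  data.frame(category = summary_rna$category,
             rna_up = summary_rna$n_up, rna_down = summary_rna$n_down,
             rna_total = summary_rna$n_total,
             rna_pct = format_pct(summary_rna$pct),
             protein_up = sp$n_up, protein_down = sp$n_down,
             protein_total = sp$n_total,
             protein_pct = format_pct(sp$pct),
             stringsAsFactors = FALSE)
}

#' Run the full classification pipeline
#'
#' Simulates or loads the inputs, scans the proteome for XPPX motifs, calls
#' fold changes on both layers, classifies every detected protein,
#' cross-references the stalling atlas if one is given, and writes the
#' per-protein inventory, the candidate funnel, and the functional-category
#' summaries. The run is a pure function of the configuration (including
#' the seed); re-running overwrites the outputs with identical content.
#'
#' Files written to `out_dir`: `inventory.tsv`, `funnel.json`,
#' `category_summary_rna.tsv`, `category_summary_protein.tsv`,
#' `category_summary_combined.tsv`, `config.yaml`, `run.log`, and (for
#' simulated runs) the generated inputs under `simulated_input/`. Output
#' tables carry a header comment with the package version and the MD5 of
#' the configuration echo.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `inventory`, `funnel`, `summary_rna`,
#'   `summary_protein`, `table1`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("efpTargets ", as.character(utils::packageVersion("efpTargets")),
      " | seed ", config$seed)

  cfg_path <- file.path(config$out_dir, "config.yaml")
  cfg_echo <- config
  cfg_echo$sim <- if (is.null(config$sim)) NULL else unclass(config$sim)
  yaml::write_yaml(unclass(cfg_echo), cfg_path)
  # hash the scientific configuration only, so identical analyses produce
  # identical outputs regardless of where they are written
  hcfg <- unclass(cfg_echo)
  hcfg$out_dir <- NULL
  htmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hcfg, htmp)
  stamp <- paste0("# efpTargets ",
                  as.character(utils::packageVersion("efpTargets")),
                  " config=", unname(tools::md5sum(htmp)))
  unlink(htmp)
  say("config echo: ", cfg_path)

  catmap <- NULL
  atlas <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    write_dataset(sim, file.path(config$out_dir, "simulated_input"))
    proteome <- sim$proteome
    rna_tab <- sim$rna
    prot_fc <- fold_change(sim$protein, protein_up = config$protein_up,
                           protein_down = config$protein_down)
    say("simulated ", config$sim$n_genes, " genes")
  } else {
    proteome <- read_proteome_fasta(config$fasta)
    rna_tab <- read_abundance_tsv(config$rna, layer = "rna")
    prot_fc <- read_protein_table(config$protein,
                                  protein_up = config$protein_up,
                                  protein_down = config$protein_down)
    say("read ", nrow(proteome), " proteins, ", nrow(rna_tab$values),
        " transcripts, ", nrow(prot_fc), " protein records")
  }
  if (!is.null(config$catmap)) catmap <- read_category_map(config$catmap)
  if (!is.null(config$atlas)) {
    atlas <- utils::read.delim(config$atlas, comment.char = "#")
    names(atlas)[1:2] <- c("protein_id", "position")
  }

  mt <- proteome_motif_table(proteome)
  say("motif scan: ", sum(mt$flags$has_xppx), " / ", nrow(mt$flags),
      " proteins with >= 1 XPPX motif (", nrow(mt$hits), " hits)")

  rna_fc <- fold_change(normalize_counts(rna_tab),
                        pseudocount = config$pseudocount,
                        rna_up = log2(config$rna_up),
                        rna_down = log2(config$rna_down))
  say("rna calls: ", sum(rna_fc$call == "up"), " up, ",
      sum(rna_fc$call == "down"), " down of ", nrow(rna_fc))
  say("protein calls: ", sum(prot_fc$call == "up"), " up, ",
      sum(prot_fc$call == "down"), " down of ", nrow(prot_fc))

  inventory <- classify_proteins(
    prot_fc, rna_fc, mt$flags,
    te_threshold = config$te_threshold,
    rna_up = log2(config$rna_up), rna_down = log2(config$rna_down),
    protein_up = config$protein_up, protein_down = config$protein_down)
  if (!is.null(atlas)) {
    inventory <- annotate_stalling(inventory, atlas, mt,
                                   window = config$stall_window)
    say("stall support: ", sum(inventory$stall_support), " proteins")
  }
  funnel <- build_funnel(inventory,
                         n_detected_rna = nrow(rna_fc),
                         n_detected_protein = nrow(inventory))
  say("funnel: ", funnel$n_protein_down, " protein-down, ",
      funnel$n_down_with_xppx, " with XPPX, ",
      funnel$n_efp_direct, " direct candidates")

  summary_rna <- summarize_categories(rna_fc, catmap)
  summary_protein <- summarize_categories(prot_fc, catmap)
  cats <- unique(c(summary_rna$category, summary_protein$category))
  table1 <- render_table1(align_categories(summary_rna, cats),
                          align_categories(summary_protein, cats))

  paths <- list(
    inventory = file.path(config$out_dir, "inventory.tsv"),
    funnel = file.path(config$out_dir, "funnel.json"),
    summary_rna = file.path(config$out_dir, "category_summary_rna.tsv"),
    summary_protein = file.path(config$out_dir,
                                "category_summary_protein.tsv"),
    table1 = file.path(config$out_dir, "category_summary_combined.tsv"),
    log = file.path(config$out_dir, "run.log"))
  write_tsv_stamped(inventory, paths$inventory, stamp)
  write_funnel_json(funnel, paths$funnel)
  write_tsv_stamped(summary_rna, paths$summary_rna, stamp)
  write_tsv_stamped(summary_protein, paths$summary_protein, stamp)
  write_tsv_stamped(table1, paths$table1, stamp)
  writeLines(log_lines, paths$log)
  invisible(list(inventory = inventory, funnel = funnel,
                 summary_rna = summary_rna,
                 summary_protein = summary_protein,
                 table1 = table1, paths = paths))
}
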