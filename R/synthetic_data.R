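# Synthetic paired transcriptome/proteome generator with planted
# XPPX-dependent translational attenuation and ground-truth labels.
#
# The causal structure being emulated: protein abundance = mRNA abundance x
# translational efficiency; in the mutant, XPPX-bearing target genes have
# their efficiency multiplied by an attenuation factor < 1, while the
# observed iTRAQ ratio is additionally dynamic-range compressed
# (observed = true^c, c in (0,1]) and perturbed by multiplicative lognormal
# measurement noise.

#' Simulation configuration
#'
#' Defaults describe a genome-scale *B. subtilis*-like experiment: ~4,237
#' genes of which ~22% carry an XPPX motif, a quarter of the genome
#' transcriptionally perturbed with log2 effects of 1.5-3, half of the
#' motif-bearing genes translationally attenuated to 0.2-0.6x efficiency in
#' the mutant, negative-binomial count noise at dispersion 0.05 over three
#' replicates per condition, 10% multiplicative proteome measurement noise,
#' and iTRAQ compression exponent 0.6.
#'
#' @param n_genes Number of genes.
#' @param frac_xppx Fraction of genes given >= 1 planted XPPX motif.
#' @param frac_rna_de Fraction of genes with a planted transcriptional
#'   change (direction up/down with equal probability).
#' @param rna_effect Length-2 range of planted |log2| transcript effects.
#' @param frac_translational Fraction of XPPX genes with planted
#'   translational attenuation in the mutant.
#' @param te_effect Length-2 range of attenuation multipliers (< 1).
#' @param nb_dispersion Negative-binomial dispersion of counts; 0 gives
#'   Poisson counts.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise on observed protein ratios; 0 disables noise.
#' @param compression Power-law compression exponent c in (0, 1]: the
#'   observed protein ratio is (true ratio)^c. c = 1 means no compression.
#' @param n_replicates RNA-seq replicates per condition. The protein table
#'   always has one pooled column per condition, mirroring a pooled iTRAQ
#'   design.
#' @param seq_len_range Length-2 range of protein lengths (residues).
#' @param baseline_log_mean,baseline_log_sd Lognormal parameters of the
#'   per-gene baseline expression level.
#' @param pfree_background If `TRUE` (default), non-motif positions carry no
#'   proline, so the planted motif flag is exactly recoverable by scanning;
#'   if `FALSE`, background residues include proline at a realistic ~4%
#'   frequency and the truth flag is taken from a scan of the generated
#'   sequences.
#' @param seed Integer seed; the dataset is a pure function of the
#'   configuration (including the seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4237,
                       frac_xppx = 0.22,
                       frac_rna_de = 0.25,
                       rna_effect = c(1.5, 3),
                       frac_translational = 0.5,
                       te_effect = c(0.2, 0.6),
                       nb_dispersion = 0.05,
                       noise_cv = 0.1,
                       compression = 0.6,
                       n_replicates = 3,
                       seq_len_range = c(80, 600),
                       baseline_log_mean = log(200),
                       baseline_log_sd = 1,
                       pfree_background = TRUE,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), frac_xppx = frac_xppx,
              frac_rna_de = frac_rna_de, rna_effect = rna_effect,
              frac_translational = frac_translational, te_effect = te_effect,
              nb_dispersion = nb_dispersion, noise_cv = noise_cv,
              compression = compression,
              n_replicates = as.integer(n_replicates),
              seq_len_range = as.integer(seq_len_range),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              pfree_background = isTRUE(pfree_background),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1,
              frac_xppx >= 0, frac_xppx <= 1,
              frac_rna_de >= 0, frac_rna_de <= 1,
              frac_translational >= 0, frac_translational <= 1,
              length(rna_effect) == 2, all(rna_effect > 0),
              rna_effect[1] <= rna_effect[2],
              length(te_effect) == 2, all(te_effect > 0), all(te_effect < 1),
              te_effect[1] <= te_effect[2],
              nb_dispersion >= 0, noise_cv >= 0,
              compression > 0, compression <= 1,
              n_replicates >= 1,
              length(seq_len_range) == 2, seq_len_range[1] >= 10,
              seq_len_range[1] <= seq_len_range[2])
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes |",
      sprintf("xppx %.2f, rna DE %.2f, translational %.2f of xppx",
              x$frac_xppx, x$frac_rna_de, x$frac_translational), "|",
      sprintf("c=%.2f, cv=%.2f, disp=%.3f, reps=%d, seed=%d",
              x$compression, x$noise_cv, x$nb_dispersion,
              x$n_replicates, x$seed), "\n")
  invisible(x)
}

#' Draw the planted ground truth
#'
#' Samples, from the current RNG state, which genes carry a motif, which are
#' transcriptionally perturbed (and how), and which motif-bearing genes are
#' translationally attenuated (and by how much), plus each gene's baseline
#' expression level. A translational target always carries a motif, by
#' construction.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per gene: `gene`, `has_xppx`,
#'   `rna_de_direction` (-1/0/1), `rna_log2_effect` (signed, 0 if no planted
#'   change), `translational_target`, `te_multiplier` (1 if untargeted),
#'   `baseline_mu`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gene <- sprintf("gene%04d", seq_len(n))
  has_xppx <- rep(FALSE, n)
  has_xppx[sample.int(n, round(config$frac_xppx * n))] <- TRUE
  dir <- rep(0L, n)
  de <- sample.int(n, round(config$frac_rna_de * n))
  dir[de] <- sample(c(-1L, 1L), length(de), replace = TRUE)
  eff <- rep(0, n)
  eff[de] <- dir[de] * stats::runif(length(de), config$rna_effect[1],
                                    config$rna_effect[2])
  target <- rep(FALSE, n)
  xi <- which(has_xppx)
  if (length(xi) > 0L) {
    target[sample(xi, round(config$frac_translational * length(xi)))] <- TRUE
  }
  te <- rep(1, n)
  te[target] <- stats::runif(sum(target), config$te_effect[1],
                             config$te_effect[2])
  data.frame(gene = gene, has_xppx = has_xppx,
             rna_de_direction = dir, rna_log2_effect = eff,
             translational_target = target, te_multiplier = te,
             baseline_mu = exp(stats::rnorm(n, config$baseline_log_mean,
                                            config$baseline_log_sd)),
             stringsAsFactors = FALSE)
}

# residues available for background positions
bg_alphabet <- function(pfree) {
  aa <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # 19 letters, no P
  if (pfree) aa else c(aa, "P")
}

#' Generate a synthetic proteome with planted XPPX motifs
#'
#' Each designated motif gene receives one to three planted XPPX windows at
#' non-overlapping positions; with the default proline-free background the
#' remaining genes contain no P-P pair at all, so a scan recovers the
#' planted flag exactly. With `pfree_background = FALSE`, background
#' residues include proline (~4%, its typical proteome frequency) and
#' `truth$has_xppx` is updated from an actual scan.
#'
#' @param config A [sim_config()].
#' @param truth Data frame from [generate_truth()].
#' @return A list: `proteome` (data frame `id`, `gene`, `sequence`; ids
#'   equal gene names) and `truth` (possibly with `has_xppx` rescanned).
#' @export
generate_proteome <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) == config$n_genes)
  n <- config$n_genes
  lens <- sample(seq(config$seq_len_range[1], config$seq_len_range[2]), n,
                 replace = TRUE)
  aa <- bg_alphabet(config$pfree_background)
  # realistic proline frequency ~4% when background prolines are allowed
  w <- if (config$pfree_background) NULL else c(rep(0.96 / 19, 19), 0.04)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  for (i in which(truth$has_xppx)) {
    L <- lens[i]
    k <- sample(1:3, 1L)
    pos <- sort(sample.int(L - 3L, min(k, L - 3L)))
    # keep windows >= 4 apart so planted PP pairs never merge
    keep <- Reduce(function(acc, p) {
      if (length(acc) == 0L || p - acc[length(acc)] >= 4L) c(acc, p) else acc
    }, pos, integer(0))
    s <- seqs[i]
    for (p in keep) {
      substr(s, p + 1L, p + 2L) <- "PP"
    }
    seqs[i] <- s
  }
  proteome <- data.frame(id = truth$gene, gene = truth$gene,
                         sequence = seqs, stringsAsFactors = FALSE)
  if (!config$pfree_background) {
    mt <- proteome_motif_table(proteome)
    truth$has_xppx <- mt$flags$has_xppx
  }
  list(proteome = proteome, truth = truth)
}

#' Generate negative-binomial transcript counts
#'
#' Wild-type means are the per-gene baselines; mutant means are scaled by
#' 2^(planted log2 effect). Counts are negative binomial with the
#' configured dispersion (Poisson when the dispersion is zero), drawn from
#' the current RNG state.
#'
#' @param config A [sim_config()].
#' @param truth Data frame from [generate_truth()].
#' @return An rna-layer [abundance_table()] with `n_replicates` columns per
#'   condition.
#' @export
generate_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  r <- config$n_replicates
  mu_w <- truth$baseline_mu
  mu_m <- truth$baseline_mu * 2^truth$rna_log2_effect
  draw <- function(mu) {
    if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  wild <- vapply(seq_len(r), function(j) draw(mu_w), numeric(n))
  mut <- vapply(seq_len(r), function(j) draw(mu_m), numeric(n))
  vals <- cbind(wild, mut)
  colnames(vals) <- c(paste0("wild_", seq_len(r)),
                      paste0("mutant_", seq_len(r)))
  rownames(vals) <- truth$gene
  abundance_table(vals, rep(c("wild", "mutant"), each = r), layer = "rna")
}

#' Generate the observed protein table
#'
#' True protein abundance is the true mRNA mean times the translational
#' efficiency (baseline efficiency 1; attenuated by the planted multiplier
#' in the mutant for target genes). The observed mutant/wild ratio is the
#' true ratio raised to the compression exponent c, times multiplicative
#' lognormal noise with the configured coefficient of variation — the
#' dynamic-range compression characteristic of iTRAQ reporter-ion ratios.
#'
#' @param config A [sim_config()].
#' @param truth Data frame from [generate_truth()].
#' @return A protein-layer [abundance_table()] with one pooled column per
#'   condition, whose mutant/wild quotient is the observed ratio.
#' @export
generate_protein_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  true_ratio <- 2^truth$rna_log2_effect * truth$te_multiplier
  obs <- true_ratio^config$compression
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    obs <- obs * exp(stats::rnorm(length(obs), -sdlog^2 / 2, sdlog))
  }
  wild <- truth$baseline_mu  # baseline translational efficiency = 1
  vals <- cbind(wild_1 = wild, mutant_1 = wild * obs)
  rownames(vals) <- truth$gene
  abundance_table(vals, c("wild", "mutant"), layer = "protein")
}

#' Simulate a complete paired dataset
#'
#' Seeds the RNG from the configuration and runs [generate_truth()],
#' [generate_proteome()], [generate_counts()], and
#' [generate_protein_table()] in order, so the result is a pure function of
#' the configuration.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `config`, `truth`, `proteome`,
#'   `rna` (rna [abundance_table()]), `protein` (protein
#'   [abundance_table()]).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- generate_truth(config)
  pg <- generate_proteome(config, truth)
  truth <- pg$truth
  rna <- generate_counts(config, truth)
  protein <- generate_protein_table(config, truth)
  structure(list(config = config, truth = truth, proteome = pg$proteome,
                 rna = rna, protein = protein),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", x$config$n_genes, "genes;",
      sum(x$truth$has_xppx), "with XPPX,",
      sum(x$truth$translational_target), "translational targets,",
      sum(x$truth$rna_de_direction != 0), "rna DE\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `proteome.fasta`, `rna_counts.tsv`, `protein_abundance.tsv`,
#' `truth.tsv`, and a `config.yaml` echo of the generating configuration.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(sim$proteome$sequence)
  names(aa) <- paste0(sim$proteome$id, " gene=", sim$proteome$gene)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
  wtab <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtab(sim$rna$values, file.path(dir, "rna_counts.tsv"))
  wtab(sim$protein$values, file.path(dir, "protein_abundance.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
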