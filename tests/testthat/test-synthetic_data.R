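test_that("sim_config validates fractions, ranges, and the compression exponent", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_xppx = 1.2))
  expect_error(sim_config(compression = 0))
  expect_error(sim_config(compression = 1.2))
  expect_error(sim_config(te_effect = c(0.5, 1.5)))
  expect_error(sim_config(n_genes = 0))
})

test_that("planted motif flags are exactly recoverable by scanning", {
  all_x <- simulate_dataset(sim_config(n_genes = 60, frac_xppx = 1, seed = 1))
  mt <- proteome_motif_table(all_x$proteome)
  expect_true(all(mt$flags$has_xppx))

  none <- simulate_dataset(sim_config(n_genes = 60, frac_xppx = 0, seed = 1))
  expect_equal(nrow(proteome_motif_table(none$proteome)$hits), 0L)

  half <- simulate_dataset(sim_config(n_genes = 1000, frac_xppx = 0.5,
                                      seed = 2))
  mt <- proteome_motif_table(half$proteome)
  expect_identical(mt$flags$has_xppx, half$truth$has_xppx)
  expect_equal(sum(mt$flags$has_xppx), 500L)
})

test_that("a realistic proline background still satisfies the truth invariant", {
  sim <- simulate_dataset(sim_config(n_genes = 300, frac_xppx = 0.3,
                                     pfree_background = FALSE, seed = 3))
  mt <- proteome_motif_table(sim$proteome)
  # truth flag comes from an actual scan in this mode
  expect_identical(mt$flags$has_xppx, sim$truth$has_xppx)
  # background prolines create extra motif genes beyond the planted 30%
  expect_gte(sum(sim$truth$has_xppx), 90L)
  expect_true(all(sim$truth$has_xppx[sim$truth$translational_target]))
})

test_that("the dataset is a pure function of the configuration", {
  a <- simulate_dataset(sim_config(n_genes = 150, seed = 99))
  b <- simulate_dataset(sim_config(n_genes = 150, seed = 99))
  expect_identical(a$rna$values, b$rna$values)
  expect_identical(a$protein$values, b$protein$values)
  expect_identical(a$proteome$sequence, b$proteome$sequence)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_dataset(sim_config(n_genes = 150, seed = 100))
  expect_false(identical(a$rna$values, c_$rna$values))
})

test_that("planted transcript effects converge to the expected mean ratio", {
  cfg <- sim_config(n_genes = 200, frac_rna_de = 1, rna_effect = c(2, 2),
                    frac_translational = 0, nb_dispersion = 0,
                    n_replicates = 200, baseline_log_mean = log(500),
                    baseline_log_sd = 0.2, seed = 4)
  sim <- simulate_dataset(cfg)
  up <- sim$truth$rna_de_direction == 1
  mw <- rowMeans(sim$rna$values[, sim$rna$condition == "wild"])
  mm <- rowMeans(sim$rna$values[, sim$rna$condition == "mutant"])
  expect_equal(mean(mm[up] / mw[up]), 4, tolerance = 0.02)
  expect_equal(mean(mm[!up] / mw[!up]), 0.25, tolerance = 0.02)
})

test_that("without planted transcriptional change, false DEG calls are rare", {
  cfg <- sim_config(n_genes = 2000, frac_rna_de = 0, frac_translational = 0,
                    nb_dispersion = 0.01, baseline_log_mean = log(300),
                    seed = 5)
  sim <- simulate_dataset(cfg)
  fc <- fold_change(normalize_counts(sim$rna))
  expect_lt(mean(fc$call != "unchanged"), 0.01)
})

test_that("protein ratios pass mRNA ratios through when nothing is planted", {
  cfg <- sim_config(n_genes = 100, frac_rna_de = 0, frac_translational = 0,
                    noise_cv = 0, compression = 1, seed = 6)
  sim <- simulate_dataset(cfg)
  fc <- fold_change(sim$protein)
  expect_equal(fc$ratio, rep(1, 100))
})

test_that("compression follows the power law on the observed ratio", {
  truth <- data.frame(gene = c("g1", "g2", "g3"),
                      has_xppx = c(TRUE, FALSE, TRUE),
                      rna_de_direction = c(-1L, 0L, 0L),
                      rna_log2_effect = c(log2(0.25), 0, 0),
                      translational_target = c(FALSE, FALSE, TRUE),
                      te_multiplier = c(1, 1, 0.4),
                      baseline_mu = c(100, 100, 100))
  cfg <- sim_config(n_genes = 3, noise_cv = 0, compression = 0.5)
  tab <- generate_protein_table(cfg, truth)
  ratio <- tab$values[, "mutant_1"] / tab$values[, "wild_1"]
  expect_equal(unname(ratio), c(0.25^0.5, 1, 0.4^0.5))

  # |log2 observed| = c * |log2 true| across a grid of true ratios
  grid <- 2^seq(-3, 3, by = 0.5)
  truth_g <- data.frame(gene = sprintf("g%02d", seq_along(grid)),
                        has_xppx = FALSE, rna_de_direction = 0L,
                        rna_log2_effect = log2(grid),
                        translational_target = FALSE, te_multiplier = 1,
                        baseline_mu = 50)
  for (cc in c(0.3, 0.6, 1)) {
    tab <- generate_protein_table(sim_config(n_genes = length(grid),
                                             noise_cv = 0, compression = cc),
                                  truth_g)
    obs <- tab$values[, "mutant_1"] / tab$values[, "wild_1"]
    expect_equal(unname(abs(log2(obs))), cc * abs(log2(grid)),
                 tolerance = 1e-12)
  }
})

test_that("a planted attenuation on a quiet gene yields a direct candidate", {
  truth <- data.frame(gene = "gX", has_xppx = TRUE, rna_de_direction = 0L,
                      rna_log2_effect = 0, translational_target = TRUE,
                      te_multiplier = 0.4, baseline_mu = 1000)
  cfg <- sim_config(n_genes = 1, noise_cv = 0, compression = 1)
  tab <- generate_protein_table(cfg, truth)
  ratio <- unname(tab$values[, "mutant_1"] / tab$values[, "wild_1"])
  expect_equal(ratio, 0.4)
  expect_equal(classify_protein(ratio, 0, TRUE)$mode, "efp_direct_candidate")
})

test_that("written datasets round-trip through the file readers", {
  sim <- simulate_dataset(sim_config(n_genes = 40, seed = 7))
  d <- tempfile()
  write_dataset(sim, d)
  pr <- read_proteome_fasta(file.path(d, "proteome.fasta"))
  expect_equal(pr$sequence, sim$proteome$sequence)
  expect_equal(pr$id, sim$proteome$id)
  rna <- read_abundance_tsv(file.path(d, "rna_counts.tsv"), "rna")
  expect_equal(rna$values, sim$rna$values)
  cfg <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfg$n_genes, 40)
  expect_equal(cfg$seed, 7)
})
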