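test_that("classify_protein applies the ordered regulatory-mode rules", {
  expect_equal(classify_protein(0.5, 0.0, TRUE)$mode, "efp_direct_candidate")
  expect_equal(classify_protein(0.5, -2.0, TRUE)$mode, "transcriptional")
  expect_equal(classify_protein(0.5, 0.0, FALSE)$mode, "secondary")
  expect_equal(classify_protein(1.0, 0.0, FALSE)$mode, "unclassified")

  # protein up, transcription up even more: per-mRNA output down
  masked <- classify_protein(2.0, 2.5, TRUE)
  expect_equal(masked$mode, "translational_attenuation_masked")
  expect_equal(masked$te_ratio, 2 / 2^2.5)

  # the masked class requires the motif and a TE ratio below threshold
  expect_equal(classify_protein(2.0, 2.5, FALSE)$mode, "unclassified")
  expect_equal(classify_protein(2.0, 0.5, TRUE)$mode, "unclassified")
})

test_that("a demonstrated mRNA decrease takes precedence over the motif", {
  # protein down + rna down + motif: transcriptional, not efp-direct
  expect_equal(classify_protein(0.4, -1.5, TRUE)$mode, "transcriptional")
  # rna exactly at the threshold is not down, so the motif rule applies
  expect_equal(classify_protein(0.4, -1, TRUE)$mode, "efp_direct_candidate")
})

test_that("missing transcript evidence is flagged but not disqualifying", {
  r <- classify_protein(0.5, NA, TRUE)
  expect_true(r$no_rna_evidence)
  expect_equal(r$rna_call, "unchanged")
  expect_equal(r$mode, "efp_direct_candidate")
  expect_equal(r$te_ratio, 0.5)
})

test_that("te_ratio equals the protein ratio over the rna ratio", {
  set.seed(21)
  for (i in 1:30) {
    pr <- runif(1, 0.1, 5)
    rl <- runif(1, -3, 3)
    expect_equal(classify_protein(pr, rl, TRUE)$te_ratio, pr / 2^rl)
  }
})

test_that("vectorized classification matches the scalar rules", {
  set.seed(22)
  n <- 300
  prot_fc <- fold_change_from_ratio(sprintf("p%03d", 1:n),
                                    exp(runif(n, log(0.2), log(5))))
  rna_fc <- data.frame(feature_id = sprintf("p%03d", 1:n),
                       ratio = 2^runif(n, -3, 3))
  rna_fc$log2fc <- log2(rna_fc$ratio)
  rna_fc$call <- call_transcript(rna_fc$log2fc)
  rna_fc$layer <- "rna"
  # drop some rna records to exercise the no-evidence path
  rna_fc <- rna_fc[-sample(n, 40), ]
  flags <- data.frame(protein_id = sprintf("p%03d", 1:n),
                      has_xppx = runif(n) < 0.3)

  inv <- classify_proteins(prot_fc, rna_fc, flags)
  for (i in sample(n, 60)) {
    rl <- rna_fc$log2fc[match(prot_fc$feature_id[i], rna_fc$feature_id)]
    one <- classify_protein(prot_fc$ratio[i], rl, flags$has_xppx[i],
                            protein_id = prot_fc$feature_id[i])
    expect_equal(inv$mode[i], one$mode)
    expect_equal(inv$te_ratio[i], one$te_ratio)
    expect_equal(inv$no_rna_evidence[i], one$no_rna_evidence)
  }
  expect_error(classify_proteins(prot_fc, rna_fc, flags[-1, ]),
               "no motif flag")
})

test_that("build_funnel counts the nested candidate sets", {
  empty <- classify_proteins(
    fold_change_from_ratio(character(0), numeric(0)),
    data.frame(feature_id = character(0), log2fc = numeric(0)),
    data.frame(protein_id = character(0), has_xppx = logical(0)))
  f0 <- build_funnel(empty, 0, 0)
  expect_true(all(unlist(f0) == 0L))

  # hand-built six calls: 2 efp-direct, 1 transcriptional (motif-bearing),
  # 1 secondary, 1 masked, 1 unclassified
  calls <- rbind(
    classify_protein(0.5, 0, TRUE, "d1"),
    classify_protein(0.4, NA, TRUE, "d2"),
    classify_protein(0.5, -2, TRUE, "t1"),
    classify_protein(0.6, 0, FALSE, "s1"),
    classify_protein(2.0, 2.5, TRUE, "m1"),
    classify_protein(1.0, 0, FALSE, "u1"))
  f <- build_funnel(calls)
  expect_equal(f$n_protein_down, 4L)
  expect_equal(f$n_down_with_xppx, 3L)
  expect_equal(f$n_efp_direct, 2L)
  expect_equal(f$n_down_mrna_driven, 1L)
  expect_equal(f$n_protein_up, 1L)
  expect_equal(f$n_detected_protein, 6L)
  expect_true(f$n_efp_direct <= f$n_down_with_xppx)
  expect_true(f$n_down_with_xppx <= f$n_protein_down)
})

test_that("efp-direct set equals protein-down AND motif AND NOT rna-down", {
  sim <- simulate_dataset(sim_config(n_genes = 800, seed = 5))
  res <- classify_dataset(sim)
  inv <- res$inventory
  direct <- inv$protein_id[inv$mode == "efp_direct_candidate"]
  algebra <- inv$protein_id[inv$protein_call == "down" & inv$has_xppx &
                              inv$rna_call != "down"]
  expect_setequal(direct, algebra)
  expect_equal(res$funnel$n_efp_direct, length(algebra))
})

test_that("tightening the protein down-threshold never grows the down set", {
  sim <- simulate_dataset(sim_config(n_genes = 600, seed = 6))
  thr <- c(0.7, 0.6, 0.5, 0.4)
  n_down <- vapply(thr, function(d) {
    classify_dataset(sim, protein_down = d)$funnel$n_protein_down
  }, integer(1))
  expect_true(all(diff(n_down) <= 0))
})

test_that("noise-free planted effects are recovered exactly", {
  cfg <- sim_config(n_genes = 500, frac_rna_de = 0, frac_translational = 0.5,
                    te_effect = c(0.2, 0.5), nb_dispersion = 0,
                    noise_cv = 0, compression = 1,
                    baseline_log_mean = log(2000), baseline_log_sd = 0.3,
                    n_replicates = 5, seed = 8)
  sim <- simulate_dataset(cfg)
  res <- classify_dataset(sim)
  m <- recovery_metrics(res$inventory, sim$truth)
  expect_equal(unname(m["precision"]), 1)
  expect_equal(unname(m["recall"]), 1)
})

test_that("planted efficiency multipliers are recovered in the TE ratio", {
  cfg <- sim_config(n_genes = 400, frac_rna_de = 0, frac_translational = 0.5,
                    nb_dispersion = 0, noise_cv = 0, compression = 1,
                    baseline_log_mean = log(5000), baseline_log_sd = 0.2,
                    n_replicates = 10, seed = 9)
  sim <- simulate_dataset(cfg)
  res <- classify_dataset(sim)
  idx <- sim$truth$translational_target
  expect_equal(res$inventory$te_ratio[idx], sim$truth$te_multiplier[idx],
               tolerance = 0.05)
})

test_that("stall-atlas support respects the matching window", {
  calls <- rbind(classify_protein(0.5, 0, TRUE, "a"),
                 classify_protein(0.5, 0, TRUE, "b"))
  hits <- rbind(scan_xppx("APPV", "a"),
                scan_xppx(paste0(strrep("G", 9), "APPV"), "b"))  # b at 10
  atlas <- data.frame(protein_id = c("a", "b"), position = c(1L, 11L))
  w0 <- annotate_stalling(calls, atlas, hits, window = 0L)
  expect_equal(w0$stall_support, c(TRUE, FALSE))
  w1 <- annotate_stalling(calls, atlas, hits, window = 1L)
  expect_equal(w1$stall_support, c(TRUE, TRUE))
  expect_warning(annotate_stalling(calls,
                                   data.frame(protein_id = "zz", position = 3L),
                                   hits),
                 "unknown protein")
})

test_that("stall support equals the all-pairs distance oracle", {
  set.seed(23)
  ids <- sprintf("p%02d", 1:30)
  calls <- do.call(rbind, lapply(ids, function(id) {
    classify_protein(runif(1, 0.3, 2), 0, TRUE, id)
  }))
  hits <- do.call(rbind, lapply(ids, function(id) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(protein_id = id, position = sample(200, k),
               motif = "APPV", kind = "xppx")
  }))
  atlas <- data.frame(protein_id = sample(ids, 40, replace = TRUE),
                      position = sample(200, 40, replace = TRUE))
  for (w in c(0L, 1L, 5L)) {
    got <- annotate_stalling(calls, atlas, hits, window = w)$stall_support
    want <- vapply(ids, function(id) {
      oracle_stall_support(hits$position[hits$protein_id == id],
                           atlas$position[atlas$protein_id == id], w)
    }, logical(1), USE.NAMES = FALSE)
    expect_equal(got, want)
  }
})
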