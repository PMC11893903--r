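test_that("invalid configuration fields fail naming the field", {
  expect_error(sim_config(wt_baseline = 1.5), "wt_baseline")
  expect_error(sim_config(n_strains = 0), "n_strains")
  expect_error(sim_config(condition_fold = -1), "condition_fold")
  expect_error(sim_config(hyper_effects = c(a = -2)), "hyper_effects")
  expect_error(sim_config(pinning_effects = c(a = 1.2)), "pinning_effects")
  expect_error(sim_config(txn_levels = c(1, 2), n_genes = 5), "txn_levels")
  expect_error(sim_config(rnh_residual = 2), "rnh_residual")
})

test_that("every generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 7)
  expect_identical(sim_flow_screen(cfg), sim_flow_screen(cfg))
  expect_identical(sim_pinning_screen(cfg), sim_pinning_screen(cfg))
  expect_identical(sim_okseq(cfg), sim_okseq(cfg))
  expect_identical(sim_foci_images(cfg), sim_foci_images(cfg))
  small <- sim_config(seed = 7, n_genes = 10, genome_length = 30000,
                      seq_depth = 1e5)
  expect_identical(sim_drip_experiment(small), sim_drip_experiment(small))
})

test_that("generators change output when the seed changes", {
  a <- sim_flow_screen(tiny_config(seed = 1))
  b <- sim_flow_screen(tiny_config(seed = 2))
  expect_false(identical(a$measurements$frac_positive,
                         b$measurements$frac_positive))
})

test_that("empty hyper_effects gives a null screen with empty truth set", {
  cfg <- tiny_config(hyper_effects = c())
  sim <- sim_flow_screen(cfg)
  expect_false(any(sim$truth$is_hit))
  expect_true(all(sim$measurements$frac_positive >= 0 &
                    sim$measurements$frac_positive <= 1))
})

test_that("planted fold-change is recovered on the log-odds scale", {
  # the generative model is logit-normal: the planted fold multiplies the
  # odds, so mean(logit) differences estimate log(fold)
  cfg <- sim_config(seed = 3, n_strains = 4, n_wt_wells = 40,
                    wells_per_plate = 44, n_replicates = 400,
                    wt_baseline = 0.01,
                    hyper_effects = c(mut001 = 10))
  sim <- sim_flow_screen(cfg)
  lg <- stats::qlogis(sim$measurements$frac_positive)
  a <- lg[sim$measurements$strain_id == "mut001"]
  w <- lg[sim$measurements$is_wt]
  est <- mean(a) - mean(w)
  se <- sqrt(stats::var(a) / length(a) + stats::var(w) / length(w))
  expect_lt(abs(est - log(10)), 3 * se)
})

test_that("pinning layout yields 48 call slots and respects planted p", {
  cfg <- tiny_config()
  sim <- sim_pinning_screen(cfg)
  slots <- dplyr::count(sim$grids, strain_id)
  expect_true(all(slots$n == 48))

  zero <- sim_pinning_screen(tiny_config(pinning_effects = c(mut001 = 0)))
  calls <- zero$grids[zero$grids$strain_id == "mut001", ]
  expect_true(all(calls$colony_size == 0))
})

test_that("pinning positives match the binomial expectation over seeds", {
  n_pos <- vapply(1:200, function(s) {
    sim <- sim_pinning_screen(
      sim_config(seed = s, n_strains = 1,
                 pinning_effects = c(mut001 = 0.5)))
    sum(sim$grids$colony_size[sim$grids$strain_id == "mut001"] > 0)
  }, numeric(1))
  # mean of Binomial(48, 0.5) is 24; 3 standard errors of the seed mean
  se <- sqrt(48 * 0.25 / length(n_pos))
  expect_lt(abs(mean(n_pos) - 24), 3 * se)
})

test_that("drip truth ratios equal the planted condition fold exactly", {
  cfg <- sim_config(seed = 2, n_genes = 15, genome_length = 45000,
                    seq_depth = 1e5, condition_fold = 2)
  sim <- sim_drip_experiment(cfg)
  tr <- tidyr::pivot_wider(sim$truth[sim$truth$treatment == "mock", ],
                           id_cols = "gene_id", names_from = "condition",
                           values_from = "hybrid_density")
  expect_equal(tr$treated / tr$control, rep(2, nrow(tr)))
})

test_that("RNase H residual of zero leaves only background in IP coverage", {
  cfg <- sim_config(seed = 4, n_genes = 15, genome_length = 45000,
                    seq_depth = 5e5, rnh_residual = 0)
  sim <- sim_drip_experiment(cfg)
  rnh <- dplyr::filter(sim$coverage, sample_id == "control_IP_RNaseH")
  # genic template bins should be indistinguishable from intergenic bins
  genic <- dplyr::filter(rnh, strand == "C")
  in_gene <- genic$start >= sim$genes$start[1] & genic$end <= sim$genes$end[1]
  plus_genes <- sim$genes[sim$genes$strand == "+", ]
  if (nrow(plus_genes) > 0) {
    g <- plus_genes[1, ]
    gene_bins <- genic$count[genic$start >= g$start & genic$end <= g$end]
    bg_bins <- genic$count[genic$start >= max(sim$genes$end)]
    expect_lt(abs(mean(gene_bins) - mean(bg_bins)),
              4 * sqrt(mean(gene_bins) / length(gene_bins) +
                         mean(bg_bins) / length(bg_bins)) + 1e-9)
  }
})

test_that("okseq truth encodes slope signs and zero slopes as ambiguous", {
  cfg <- tiny_config()
  sim <- sim_okseq(cfg, zero_fraction = 0.2)
  expect_true(all(sim$truth$fork_direction[sim$truth$slope_per_kb > 0] == "right"))
  expect_true(all(sim$truth$fork_direction[sim$truth$slope_per_kb < 0] == "left"))
  expect_true(all(sim$truth$fork_direction[sim$truth$slope_per_kb == 0] ==
                    "ambiguous"))
  expect_equal(sum(sim$truth$slope_per_kb == 0), 8)
})

test_that("noiseless okseq profiles reproduce the planted slope exactly", {
  cfg <- tiny_config(okseq_noise_sd = 1e-12)
  sim <- sim_okseq(cfg)
  fit <- okseq_slope(sim$profile, c(sim$truth$start[1], sim$truth$end[1]))
  expect_equal(fit$slope_per_kb, sim$truth$slope_per_kb[1], tolerance = 1e-6)
})

test_that("foci generator plants the advertised counts and zero stays zero", {
  cfg <- tiny_config(foci_per_nucleus = 0L)
  sim <- sim_foci_images(cfg, noiseless = TRUE)
  expect_true(all(sim$truth$n_foci == 0))
  expect_equal(nrow(sim$foci_truth), 0)

  cfg2 <- tiny_config()
  sim2 <- sim_foci_images(cfg2)
  tally <- dplyr::count(sim2$foci_truth, image, nucleus_id)
  joined <- dplyr::left_join(sim2$truth, tally,
                             by = c("image", "nucleus_id"))
  joined$n[is.na(joined$n)] <- 0L
  expect_equal(joined$n, joined$n_foci)
  # nuclei non-overlapping by construction
  for (img in unique(sim2$truth$image)) {
    tr <- sim2$truth[sim2$truth$image == img, ]
    d <- as.matrix(stats::dist(tr[, c("cx", "cy")]))
    diag(d) <- Inf
    expect_true(all(d > 2 * tr$radius[1]))
  }
})
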