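test_that("the occupancy ratio is the input/IP spike-fraction ratio", {
  expect_equal(occupancy_ratio(list(n_spike = 5000, n_total = 1e5),
                               list(n_spike = 5000, n_total = 1e5)), 1)
  expect_equal(occupancy_ratio(list(n_spike = 5000, n_total = 1e5),
                               list(n_spike = 1000, n_total = 1e5)), 5)
  # depth invariance of the IP library
  expect_equal(occupancy_ratio(list(n_spike = 5000, n_total = 1e5),
                               list(n_spike = 10000, n_total = 1e6)), 5)
  expect_error(occupancy_ratio(list(n_spike = 0, n_total = 1e5),
                               list(n_spike = 10, n_total = 1e5)), "spike")
})

test_that("calibration reproduces counts at unit scale and cancels depth", {
  track <- tibble::tibble(chrom = "c", start = c(0, 20), end = c(20, 40),
                          count = c(7, 3), genome = "experimental")
  cal <- calibrate(track, or_value = 1, ip_total = 1e6)
  expect_equal(cal$calibrated, track$count)

  # doubling depth uniformly (counts and total) leaves calibrated unchanged
  cal2 <- calibrate(dplyr::mutate(track, count = count * 2), 1, 2e6)
  expect_equal(cal2$calibrated, cal$calibrated)
  expect_error(calibrate(track, 0, 1e6), "or_value")
  expect_error(calibrate(track, 1, 0), "ip_total")
})

test_that("gene densities use the template-strand convention and edge weights", {
  bins <- tidyr::expand_grid(strand = c("W", "C"),
                             start = seq(0, 80, by = 20)) |>
    dplyr::mutate(chrom = "c", end = start + 20, calibrated = 0)
  # signal only on C: a + gene must be fully template-specific
  bins$calibrated[bins$strand == "C"] <- 10
  gene_plus <- tibble::tibble(gene_id = "gp", chrom = "c", start = 20,
                              end = 60, strand = "+")
  d <- gene_density(bins, gene_plus)
  expect_equal(d$specificity, 1)
  expect_equal(d$template_density, 10 * 40 / 20 / 40)  # 10 per 20-bp bin

  gene_minus <- dplyr::mutate(gene_plus, strand = "-")
  dm <- gene_density(bins, gene_minus)
  expect_equal(dm$specificity, 0)

  # equal signal both strands
  bins2 <- dplyr::mutate(bins, calibrated = 4)
  expect_equal(gene_density(bins2, gene_plus)$specificity, 0.5)

  # partial bins: gene covering 2.5 bins of known counts
  bins3 <- bins
  bins3$calibrated[bins3$strand == "C"] <- c(2, 4, 6, 8, 10)
  gene_frac <- tibble::tibble(gene_id = "gf", chrom = "c", start = 0,
                              end = 50, strand = "+")
  # oracle: full bins 2 and 4, half of bin 6 -> (2 + 4 + 3) / 50 bp
  expect_equal(gene_density(bins3, gene_frac)$template_density,
               (2 + 4 + 6 * 0.5) / 50)
  expect_error(gene_density(bins, dplyr::mutate(gene_plus, chrom = "nope")),
               "absent")
})

test_that("RNase H sensitivity and fold-change identities hold", {
  expect_equal(rnase_h_sensitivity(2, 0), 1)
  expect_equal(rnase_h_sensitivity(2, 2), 0)
  expect_warning(out <- rnase_h_sensitivity(0, 1), "zero")
  expect_true(is.na(out))

  expect_equal(density_fold_change(3, 3), 1)
  expect_equal(density_fold_change(0, 0), 1)
  expect_equal(density_fold_change(1.99, 0.99, pseudocount = 0.01), 2)
  expect_error(density_fold_change(-1, 1), ">= 0")
})

test_that("planted calibration parameters are recovered from simulation", {
  cfg <- sim_config(seed = 5, n_genes = 60, genome_length = 180000,
                    seq_depth = 1e6)
  sim <- sim_drip_experiment(cfg)
  cal <- calibrate_drip(sim$coverage, sim$spike_counts)
  dens <- cal$tracks |>
    dplyr::group_by(sample_id) |>
    dplyr::group_modify(function(df, key) gene_density(df, sim$genes)) |>
    dplyr::ungroup()
  cm <- dens[dens$sample_id == "control_IP_mock", ]
  tm <- dens[dens$sample_id == "treated_IP_mock", ]
  cr <- dens[dens$sample_id == "control_IP_RNaseH", ]
  fold <- stats::median(density_fold_change(tm$template_density,
                                            cm$template_density))
  expect_lt(abs(fold - cfg$condition_fold), 0.2)
  sens <- stats::median(rnase_h_sensitivity(cm$template_density,
                                            cr$template_density))
  expect_lt(abs(sens - 0.88), 0.06)  # residual 0.1 over a small background
  expect_gte(mean(cm$specificity), 0.9)
})

test_that("calibrated signal scales linearly with true occupancy", {
  cfg <- sim_config(seed = 6, n_genes = 60, genome_length = 180000,
                    seq_depth = 1e6)
  sim <- sim_drip_experiment(cfg)
  cal <- calibrate_drip(sim$coverage, sim$spike_counts)
  cm <- cal$tracks[cal$tracks$sample_id == "control_IP_mock", ]
  d <- gene_density(cm, sim$genes)
  truth <- sim$truth[sim$truth$condition == "control" &
                       sim$truth$treatment == "mock", ]
  j <- dplyr::inner_join(d, truth, by = "gene_id")
  fit <- stats::lm(log(template_density) ~ log(hybrid_density), data = j)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.1)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("metagene rows are oriented, scaled and ranked", {
  bins <- tidyr::expand_grid(strand = c("W", "C"),
                             start = seq(0, 1980, by = 20)) |>
    dplyr::mutate(chrom = "c", end = start + 20, calibrated = 1)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "c",
                          start = c(600, 1200), end = c(1000, 1600),
                          strand = c("+", "-"))
  mg <- metagene(bins, genes, flank_bp = 100, body_bins = 10)
  expect_equal(dim(mg$template), c(2, 2 * 5 + 10))
  # uniform signal -> constant rows
  expect_true(all(mg$template == 1))
  expect_true(all(mg$nontemplate == 1))

  # gradient signal: a minus-strand gene row equals the reversed
  # computation of the mirrored plus-strand gene
  bins_grad <- dplyr::mutate(bins, calibrated = start / 20)
  g_plus <- tibble::tibble(gene_id = "gp", chrom = "c", start = 600,
                           end = 1000, strand = "+")
  g_minus <- dplyr::mutate(g_plus, gene_id = "gm", strand = "-")
  mp <- metagene(bins_grad, g_plus, flank_bp = 100, body_bins = 10)
  # mirror the coverage around the gene midpoint and recompute as +
  mirror <- dplyr::mutate(bins_grad,
                          start2 = 1600 - end, end2 = 1600 - start,
                          strand = ifelse(strand == "W", "C", "W")) |>
    dplyr::transmute(strand, chrom, start = start2, end = end2, calibrated) |>
    dplyr::arrange(strand, start)
  mm <- metagene(mirror, g_plus, flank_bp = 100, body_bins = 10)
  mg_minus <- metagene(bins_grad, g_minus, flank_bp = 100, body_bins = 10)
  expect_equal(unname(mg_minus$template[1, ]), unname(mm$template[1, ]),
               tolerance = 1e-9)

  # ranking: gene with higher template density comes first
  bins_rank <- bins
  bins_rank$calibrated[bins_rank$strand == "C" & bins_rank$start >= 1200 &
                         bins_rank$start < 1600] <- 50
  genes_rank <- tibble::tibble(gene_id = c("low", "high"), chrom = "c",
                               start = c(200, 1200), end = c(600, 1600),
                               strand = "+")
  mr <- metagene(bins_rank, genes_rank, flank_bp = 100, body_bins = 10)
  expect_equal(mr$row_order, c("high", "low"))
})

test_that("okseq slopes are fitted exactly on clean signal", {
  prof <- tibble::tibble(position = seq(0, 1000, by = 100))
  prof$signal <- 2 * prof$position / 1000 + 1
  fit <- okseq_slope(prof)
  expect_equal(fit$slope_per_kb, 2, tolerance = 1e-9)

  flat <- dplyr::mutate(prof, signal = 3)
  expect_equal(okseq_slope(flat)$slope_per_kb, 0, tolerance = 1e-9)
  expect_error(okseq_slope(prof[1:2, ]), "3 points")
})

test_that("orientation classification crosses fork direction with strand", {
  # rightward fork (positive slope under the default convention)
  calls <- classify_orientation(slope = c(2, 2, -2, -2),
                                slope_se = 0.01,
                                gene_strand = c("+", "-", "+", "-"))
  expect_equal(calls$orientation, c("CD", "HO", "HO", "CD"))
  # convention flip inverts every call
  flipped <- classify_orientation(c(2, 2, -2, -2), 0.01,
                                  c("+", "-", "+", "-"),
                                  sign_convention = "positive_slope_means_leftward")
  expect_equal(flipped$orientation, c("HO", "CD", "CD", "HO"))
  # flat slopes inside the ambiguity band
  amb <- classify_orientation(0.1, slope_se = 0.2, gene_strand = "+")
  expect_equal(amb$orientation, "ambiguous")
})

test_that("noiseless synthetic OK-seq is classified perfectly", {
  cfg <- tiny_config(okseq_noise_sd = 1e-9)
  sim <- sim_okseq(cfg)
  win <- dplyr::mutate(sim$truth[, c("interval", "start", "end")],
                       strand = rep(c("+", "-"), length.out = dplyr::n()))
  calls <- orientation_from_profile(sim$profile, win)
  expected <- ifelse((sim$truth$fork_direction == "right") ==
                       (win$strand == "+"), "CD", "HO")
  expect_equal(calls$orientation, expected)
})

test_that("qPCR percent IP follows the efficiency model", {
  rec <- tibble::tibble(ct_input = 20, ct_ip = c(20, 19, 20 + log2(20)))
  out <- qpcr_percent_ip(rec)
  expect_equal(out$percent_ip, c(5, 10, 0.25), tolerance = 1e-9)
  expect_error(qpcr_percent_ip(rec, efficiency = 2.5), "efficiency")
  expect_error(qpcr_percent_ip(rec, efficiency = 1), "efficiency")
})

test_that("spike-adjusted percent IP normalizes out global efficiency", {
  expect_equal(qpcr_adjust(2, 50, 100), 4)
  expect_equal(qpcr_adjust(3, 100, 100), 3)
  # halved global IP efficiency: locus and spike both halve
  expect_equal(qpcr_adjust(1, 25, 100), qpcr_adjust(2, 50, 100))
  expect_error(qpcr_adjust(1, 0), "positive")
})

test_that("intergenic calibrated signal stays at the planted background", {
  cfg <- sim_config(seed = 8, n_genes = 40, genome_length = 120000,
                    seq_depth = 1e6)
  sim <- sim_drip_experiment(cfg)
  cal <- calibrate_drip(sim$coverage, sim$spike_counts)
  cm <- cal$tracks[cal$tracks$sample_id == "control_IP_mock", ]
  # intergenic windows: the gap between consecutive genes, trimmed by a bin
  gaps <- tibble::tibble(
    gene_id = paste0("gap", seq_len(nrow(sim$genes) - 1)),
    chrom = sim$genes$chrom[1],
    start = sim$genes$end[-nrow(sim$genes)] + cfg$bin_width,
    end = sim$genes$start[-1] - cfg$bin_width,
    strand = "+"
  )
  gaps <- gaps[gaps$end - gaps$start >= 3 * cfg$bin_width, ]
  gd <- gene_density(cm, gaps)
  inter <- mean(c(gd$template_density, gd$nontemplate_density))
  # convert the truth background into calibrated units via the fitted
  # truth-to-calibrated scale on genic template signal
  truth <- sim$truth[sim$truth$condition == "control" &
                       sim$truth$treatment == "mock", ]
  genic <- gene_density(cm, sim$genes)
  j <- dplyr::inner_join(genic, truth, by = "gene_id")
  scale_factor <- stats::median(
    j$template_density / (j$hybrid_density + cfg$background_density))
  expect_lte(inter, cfg$background_density * scale_factor * 1.2)
})

test_that("orientation-independent hybrid gains show no CD vs HO difference", {
  # the generator plants the same condition fold on every gene; classifying
  # genes CD/HO from an OK-seq profile over the same coordinates must then
  # find no fold-change difference between the orientation classes
  pass <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, n_genes = 30, genome_length = 90000,
                      seq_depth = 3e5, okseq_n_intervals = 6,
                      okseq_interval_bp = 15000L)
    sim <- sim_drip_experiment(cfg)
    cal <- calibrate_drip(sim$coverage, sim$spike_counts)
    dm <- function(id) gene_density(cal$tracks[cal$tracks$sample_id == id, ],
                                    sim$genes)
    fold <- density_fold_change(dm("treated_IP_mock")$template_density,
                                dm("control_IP_mock")$template_density)
    ok <- sim_okseq(cfg)
    mid <- (sim$genes$start + sim$genes$end) / 2
    iv <- pmin(floor(mid / cfg$okseq_interval_bp) + 1, nrow(ok$truth))
    win <- tibble::tibble(gene_id = sim$genes$gene_id,
                          start = ok$truth$start[iv], end = ok$truth$end[iv],
                          strand = sim$genes$strand)
    calls <- orientation_from_profile(ok$profile, win)
    cd <- fold[calls$orientation == "CD"]
    ho <- fold[calls$orientation == "HO"]
    if (length(cd) < 3 || length(ho) < 3) return(NA)
    suppressWarnings(stats::wilcox.test(cd, ho)$p.value) > 0.05
  }, logical(1))
  expect_gte(mean(pass, na.rm = TRUE), 0.9)
})
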