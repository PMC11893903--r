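perfect_series <- function(scale = 1000, amounts = c(1, 0.5, 0.25, 0.125)) {
  tibble::tibble(amount = amounts, intensity = scale * amounts)
}

test_that("the standard curve recovers a proportional series exactly", {
  std <- fit_standard(perfect_series())
  expect_equal(std$slope, 1, tolerance = 1e-9)
  expect_equal(std$intercept, log(1000), tolerance = 1e-9)
  expect_equal(glance(std)$r_squared, 1, tolerance = 1e-9)

  # doubling all intensities shifts the intercept, not inferred ratios
  std2 <- fit_standard(dplyr::mutate(perfect_series(),
                                     intensity = intensity * 2))
  expect_equal(std2$slope, std$slope, tolerance = 1e-9)
  expect_equal(std2$intercept, std$intercept + log(2), tolerance = 1e-9)
})

test_that("a saturated top point is dropped and the slope refitted", {
  s <- perfect_series(amounts = c(1, 0.5, 0.25, 0.125, 0.0625))
  s$intensity[1] <- s$intensity[2] * 1.05  # saturation at the top load
  std <- fit_standard(s, r2_min = 0.995)
  expect_false(std$used[1])
  # oracle: refit excluding the saturated point
  oracle <- stats::lm(log(intensity) ~ log(amount), data = s[-1, ])
  expect_equal(std$slope, unname(stats::coef(oracle)[2]), tolerance = 1e-9)

  expect_error(fit_standard(perfect_series(amounts = c(1, 0.5))), "3 dilution")
})

dotblot_data <- function(levels = c(ref = 1, a = 3, b = 1)) {
  sim_dotblot(seed = 1, true_levels = levels, noise_sd = 0)$series
}

test_that("relative levels interpolate to the planted ratios", {
  lv <- relative_level(dotblot_data(), reference_id = "ref")
  expect_equal(lv$relative_level[lv$sample_id == "ref"], 1)
  expect_equal(lv$relative_level[lv$sample_id == "a"], 3, tolerance = 1e-9)
  expect_equal(lv$relative_level[lv$sample_id == "b"], 1, tolerance = 1e-9)
})

test_that("relative levels are invariant to channel and sample rescaling", {
  base <- dotblot_data()
  lv0 <- relative_level(base, "ref")
  # common multiplicative rescale of one sample's two channels
  resc <- dplyr::mutate(base, intensity = ifelse(sample_id == "a",
                                                 intensity * 2, intensity))
  lv1 <- relative_level(resc, "ref", extrapolate = TRUE)
  expect_equal(lv1$relative_level, lv0$relative_level, tolerance = 1e-9)
  # membrane-wide exposure rescale of one channel (reference included)
  expo <- dplyr::mutate(base, intensity = ifelse(channel == "S9.6",
                                                 intensity * 7, intensity))
  lv2 <- relative_level(expo, "ref")
  expect_equal(lv2$relative_level, lv0$relative_level, tolerance = 1e-9)
})

test_that("out-of-range intensities are flagged", {
  base <- dotblot_data(levels = c(ref = 1, hot = 40))
  lv <- relative_level(base, "ref", extrapolate = TRUE)
  expect_true(lv$flagged[lv$sample_id == "hot"])
  expect_false(lv$flagged[lv$sample_id == "ref"])
})

test_that("quartile assignment makes near-equal blocks with Q1 highest", {
  lv8 <- tibble::tibble(strain_id = letters[1:8], relative_level = 8:1)
  q8 <- assign_quartiles(lv8)
  expect_equal(as.integer(table(q8$quartile)), rep(2L, 4))
  expect_equal(q8$quartile[q8$strain_id == "a"], factor("Q1", paste0("Q", 1:4)))

  lv39 <- tibble::tibble(strain_id = paste0("m", 1:39),
                         relative_level = stats::runif(39))
  q39 <- assign_quartiles(lv39)
  sizes <- as.integer(table(q39$quartile))
  expect_equal(sum(sizes), 39)
  expect_lte(diff(range(sizes)), 1)
  top <- lv39$strain_id[which.max(lv39$relative_level)]
  expect_equal(as.character(q39$quartile[q39$strain_id == top]), "Q1")

  expect_error(assign_quartiles(lv8[1:3, ]), "at least 4")
})

test_that("quartiles are equivariant under permutation of input rows", {
  set.seed(31)
  lv <- tibble::tibble(strain_id = paste0("m", 1:17),
                       relative_level = stats::rlnorm(17))
  q1 <- assign_quartiles(lv)
  perm <- lv[sample(nrow(lv)), ]
  q2 <- assign_quartiles(perm)
  expect_equal(dplyr::arrange(q1, strain_id), dplyr::arrange(q2, strain_id))
})

test_that("DE classification applies strict thresholds and partitions", {
  expect_equal(as.character(classify_de(1.0, 0.01)), "up")
  expect_equal(as.character(classify_de(-1.0, 0.2)), "unaffected")
  expect_equal(as.character(classify_de(0.58, 0.01)), "unaffected")
  expect_equal(as.character(classify_de(-0.59, 0.049)), "down")

  set.seed(32)
  de <- tibble::tibble(log2_fc = stats::rnorm(500, 0, 1),
                       p_value = stats::runif(500))
  out <- classify_de(de)
  expect_true(all(!is.na(out$category)))
  expect_equal(nrow(out), 500)
  # consistency with the rule, checked independently
  manual <- ifelse(out$log2_fc > 0.58 & out$p_value < 0.05, "up",
                   ifelse(out$log2_fc < -0.58 & out$p_value < 0.05, "down",
                          "unaffected"))
  expect_equal(as.character(out$category), manual)
})

test_that("level-recombination correlation behaves at the extremes", {
  lv <- tibble::tibble(strain_id = paste0("m", 1:10),
                       relative_level = 1:10)
  rec_up <- tibble::tibble(strain_id = paste0("m", 1:10),
                           median_index = (1:10) * 7)
  expect_equal(correlate_levels_recombination(lv, rec_up)$rho, 1)
  rec_dn <- dplyr::mutate(rec_up, median_index = rev(median_index))
  expect_equal(correlate_levels_recombination(lv, rec_dn)$rho, -1)

  rec_const <- dplyr::mutate(rec_up, median_index = 5)
  expect_warning(out <- correlate_levels_recombination(lv, rec_const),
                 "constant")
  expect_true(out$flagged)
  expect_error(correlate_levels_recombination(lv[1:3, ], rec_up[1:3, ]),
               "at least 5")
})

test_that("independent levels and indices correlate near zero over seeds", {
  rhos <- vapply(1:60, function(s) {
    set.seed(s)
    lv <- tibble::tibble(strain_id = paste0("m", 1:39),
                         relative_level = stats::rlnorm(39))
    rec <- tibble::tibble(strain_id = paste0("m", 1:39),
                          median_index = stats::runif(39, 0, 100))
    correlate_levels_recombination(lv, rec)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 / sqrt(38 * length(rhos)) * 3)
})

test_that("stratified fold-changes summarise and compare categories", {
  fc <- tibble::tibble(
    fold_change = c(2, 1, 0.5),
    category = factor(c("up", "unaffected", "down"),
                      levels = c("up", "down", "unaffected"))
  )
  out <- stratified_fold_change(fc)
  expect_equal(out$summary$median[out$summary$category == "up"], 2)
  expect_equal(out$summary$n, c(1, 1, 1))

  # planted shift: down category at half the fold-change
  set.seed(33)
  fc2 <- tibble::tibble(
    fold_change = c(stats::rlnorm(60, log(0.5), 0.3),
                    stats::rlnorm(60, log(1), 0.3)),
    category = factor(rep(c("down", "unaffected"), each = 60),
                      levels = c("up", "down", "unaffected"))
  )
  expect_warning(out2 <- stratified_fold_change(fc2), "up")
  p <- out2$tests$p_value[out2$tests$category_a == "down" &
                            out2$tests$category_b == "unaffected"]
  expect_lt(p, 0.05)
})

test_that("rank-sum p-values are calibrated when categories share a distribution", {
  ps <- vapply(1:40, function(s) {
    set.seed(s + 100)
    fc <- tibble::tibble(
      fold_change = stats::rlnorm(80),
      category = factor(rep(c("up", "unaffected"), each = 40),
                        levels = c("up", "unaffected"))
    )
    stratified_fold_change(fc)$tests$p_value
  }, numeric(1))
  # roughly uniform: around 5% of null p-values fall below 0.05
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
})
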