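#' Fit a dot-blot standard curve from a reference dilution series
#'
#' Fits intensity versus loaded DNA amount for one detection channel on a
#' log-log scale by least squares. The linear range is selected
#' automatically: while the fit's R-squared stays below `r2_min` and more
#' than three points remain, the highest-amount point (where membrane
#' saturation occurs) is dropped and the line refitted.
#'
#' @param series Tibble with `amount` (relative DNA amounts loaded,
#'   decreasing dilutions) and `intensity` columns for one channel of the
#'   reference sample.
#' @param r2_min R-squared required to accept the fitted range.
#' @return An object of class `dotblot_standard` with elements `slope`,
#'   `intercept` (log-log scale), `r_squared`, `used` (logical per input
#'   point) and `data`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_standard <- function(series, r2_min = 0.98) {
  check_columns(series, c("amount", "intensity"), "series")
  usable <- series$amount > 0 & series$intensity > 0
  if (sum(usable) < 3)
    stop("need at least 3 dilution points with positive intensity", call. = FALSE)
  dat <- series[usable, ]
  used <- rep(TRUE, nrow(dat))

  fit_once <- function(keep) {
    fit <- stats::lm(log(intensity) ~ log(amount), data = dat[keep, ])
    list(fit = fit, r2 = suppressWarnings(summary(fit))$r.squared)
  }
  cur <- fit_once(used)
  while (cur$r2 < r2_min && sum(used) > 3) {
    used[which(used)[which.max(dat$amount[used])]] <- FALSE
    cur <- fit_once(used)
  }

  co <- stats::coef(cur$fit)
  out_used <- rep(FALSE, nrow(series))
  out_used[which(usable)] <- used
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    r_squared = cur$r2, used = out_used, data = series
  ), class = "dotblot_standard")
}

#' @export
print.dotblot_standard <- function(x, ...) {
  cat("<dotblot_standard> log(intensity) =", signif(x$intercept, 4), "+",
      signif(x$slope, 4), "* log(amount);  R^2 =", signif(x$r_squared, 4),
      " (", sum(x$used), "/", length(x$used), " points )\n")
  invisible(x)
}

# invert the standard: estimated relative amount for observed intensities
standard_invert <- function(standard, intensity) {
  exp((log(intensity) - standard$intercept) / standard$slope)
}

#' Relative DNA:RNA hybrid level of samples from dot-blot series
#'
#' Interpolates each sample's hybrid (S9.6) and total-DNA (dsDNA) amounts
#' from channel-specific standard curves fitted on a reference sample, and
#' reports the hybrid-per-DNA ratio relative to that reference (whose level
#' is exactly 1). The statistic is invariant to any common multiplicative
#' rescaling of a sample's two channels and to membrane-wide exposure
#' changes within a channel.
#'
#' @param data Tibble with `sample_id`, `channel` (values in
#'   `hybrid_channel` / `dna_channel`), `amount`, `intensity`.
#' @param reference_id Sample used as standard and unit reference.
#' @param hybrid_channel,dna_channel Channel labels.
#' @param extrapolate Allow intensities outside the standards' fitted
#'   range; such points are flagged either way.
#' @param r2_min Passed to [fit_standard()].
#' @return Tibble `sample_id`, `hybrid_amount`, `dna_amount`,
#'   `relative_level`, `flagged`.
#' @export
relative_level <- function(data, reference_id, hybrid_channel = "S9.6",
                           dna_channel = "dsDNA", extrapolate = FALSE,
                           r2_min = 0.98) {
  check_columns(data, c("sample_id", "channel", "amount", "intensity"), "data")
  for (id in unique(data$sample_id)) {
    have <- unique(data$channel[data$sample_id == id])
    if (!all(c(hybrid_channel, dna_channel) %in% have))
      stop("sample ", id, " lacks one of the channels ",
           hybrid_channel, "/", dna_channel, call. = FALSE)
  }
  ref <- dplyr::filter(data, .data$sample_id == reference_id)
  if (!nrow(ref)) stop("reference sample not found: ", reference_id, call. = FALSE)

  standards <- list(
    hyb = fit_standard(dplyr::filter(ref, .data$channel == hybrid_channel),
                       r2_min = r2_min),
    dna = fit_standard(dplyr::filter(ref, .data$channel == dna_channel),
                       r2_min = r2_min)
  )

  est_amount <- function(series, std) {
    rng <- range(std$data$intensity[std$used])
    inside <- series$intensity >= rng[1] & series$intensity <= rng[2]
    use <- if (extrapolate) rep(TRUE, nrow(series)) else inside
    if (!any(use))
      stop("all intensities outside the standard range; set extrapolate = TRUE",
           call. = FALSE)
    # each dilution point yields an estimate of the sample's concentration
    # relative to the reference: inferred amount / loaded amount
    est <- standard_invert(std, series$intensity[use]) / series$amount[use]
    list(value = exp(mean(log(est))), flagged = !all(inside))
  }

  per_sample <- purrr::map_dfr(unique(data$sample_id), function(id) {
    hyb <- est_amount(dplyr::filter(data, .data$sample_id == id,
                                    .data$channel == hybrid_channel),
                      standards$hyb)
    dna <- est_amount(dplyr::filter(data, .data$sample_id == id,
                                    .data$channel == dna_channel),
                      standards$dna)
    tibble::tibble(sample_id = id, hybrid_amount = hyb$value,
                   dna_amount = dna$value,
                   ratio = hyb$value / dna$value,
                   flagged = hyb$flagged || dna$flagged)
  })
  ref_ratio <- per_sample$ratio[per_sample$sample_id == reference_id]
  per_sample |>
    dplyr::mutate(relative_level = .data$ratio / ref_ratio) |>
    dplyr::select("sample_id", "hybrid_amount", "dna_amount",
                  "relative_level", "flagged")
}

#' Split samples into quartiles by hybrid level
#'
#' Ranks samples by `level_col` descending and splits them into four
#' contiguous rank blocks of near-equal size (differing by at most one;
#' earlier quartiles take the remainder). Q1 holds the highest hybrid
#' levels. Ties are broken by stable input order.
#'
#' @param levels Tibble with an id column and a level column.
#' @param id_col,level_col Column names.
#' @return Tibble `id_col`, level column, `quartile` (factor Q1-Q4).
#' @export
assign_quartiles <- function(levels, id_col = "strain_id",
                             level_col = "relative_level") {
  check_columns(levels, c(id_col, level_col), "levels")
  n <- nrow(levels)
  if (n < 4) stop("need at least 4 samples to form quartiles", call. = FALSE)
  sizes <- n %/% 4 + (seq_len(4) <= n %% 4)
  ord <- order(-levels[[level_col]])  # stable for ties
  out <- levels[ord, c(id_col, level_col)]
  out$quartile <- factor(rep(paste0("Q", 1:4), times = sizes),
                         levels = paste0("Q", 1:4))
  out
}

#' Classify transcripts by differential-expression thresholds
#'
#' Applies the printed post-hoc thresholds to a differential-expression
#' table: `up` when `log2_fc > fc_thresh` and `p_value < p_thresh`, `down`
#' when `log2_fc < -fc_thresh` and `p_value < p_thresh`, otherwise
#' `unaffected`. Inequalities are strict; a transcript exactly at the
#' fold-change threshold is unaffected.
#'
#' @param de Tibble with `log2_fc` and `p_value` (e.g. a DESeq2 results
#'   table renamed), or a numeric vector of log2 fold-changes (then
#'   `p_value` must be given).
#' @param p_value Numeric vector when `de` is a vector.
#' @param fc_thresh,p_thresh Thresholds (|log2 FC| > 0.58, p < 0.05 by
#'   default).
#' @return `de` with a `category` factor appended, or a factor vector.
#' @export
classify_de <- function(de, p_value = NULL, fc_thresh = 0.58, p_thresh = 0.05) {
  if (is.data.frame(de)) {
    check_columns(de, c("log2_fc", "p_value"), "de")
    lfc <- de$log2_fc; p <- de$p_value
  } else {
    lfc <- de; p <- p_value
  }
  stopifnot(all(is.finite(lfc)), all(is.finite(p)))
  cat_ <- factor(
    dplyr::case_when(
      lfc > fc_thresh & p < p_thresh ~ "up",
      lfc < -fc_thresh & p < p_thresh ~ "down",
      TRUE ~ "unaffected"
    ),
    levels = c("up", "down", "unaffected")
  )
  if (is.data.frame(de)) dplyr::mutate(de, category = cat_) else cat_
}

#' Rank correlation between hybrid levels and recombination metrics
#'
#' Spearman correlation (two-sided) between per-strain hybrid levels and a
#' recombination metric (index or frequency), joined on the id column.
#'
#' @param levels Tibble with id and `level_col`.
#' @param recombination Tibble with id and `metric_col`.
#' @param id_col,level_col,metric_col Column names.
#' @return Tibble with `rho`, `p_value`, `n`, `flagged` (TRUE when either
#'   vector is constant and the correlation is undefined).
#' @export
correlate_levels_recombination <- function(levels, recombination,
                                           id_col = "strain_id",
                                           level_col = "relative_level",
                                           metric_col = "median_index") {
  check_columns(levels, c(id_col, level_col), "levels")
  check_columns(recombination, c(id_col, metric_col), "recombination")
  joined <- dplyr::inner_join(levels[, c(id_col, level_col)],
                              recombination[, c(id_col, metric_col)],
                              by = id_col)
  if (nrow(joined) < 5)
    stop("need at least 5 paired observations; got ", nrow(joined), call. = FALSE)
  x <- joined[[level_col]]; y <- joined[[metric_col]]
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input vector: Spearman correlation undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = nrow(joined), flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(joined), flagged = FALSE)
}

#' Stratify hybrid fold-changes by expression category
#'
#' Summarises per-gene hybrid fold-changes within each differential
#' expression category (Tukey box statistics: quartiles and 1.5 IQR
#' whiskers) and compares every pair of categories with a two-sided
#' rank-sum test. Empty categories are skipped with a warning.
#'
#' @param fold_changes Tibble with `fold_change` and `category` columns
#'   (see [classify_de()]).
#' @return A list with `summary` (per-category Tukey box statistics) and
#'   `tests` (pairwise Wilcoxon rank-sum p-values).
#' @export
stratified_fold_change <- function(fold_changes) {
  check_columns(fold_changes, c("fold_change", "category"), "fold_changes")
  cats <- if (is.factor(fold_changes$category))
    levels(fold_changes$category) else sort(unique(fold_changes$category))
  present <- cats[cats %in% fold_changes$category]
  missing_cats <- setdiff(cats, present)
  if (length(missing_cats))
    warning("empty categories skipped: ", paste(missing_cats, collapse = ", "))

  summary <- fold_changes |>
    dplyr::filter(.data$category %in% present) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$fold_change, 0.25, names = FALSE),
      median = stats::median(.data$fold_change),
      q3 = stats::quantile(.data$fold_change, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      whisker_low = purrr::map2_dbl(.data$q1, .data$q3, function(q1, q3) q1 - 1.5 * (q3 - q1)),
      whisker_high = purrr::map2_dbl(.data$q1, .data$q3, function(q1, q3) q3 + 1.5 * (q3 - q1))
    )

  pairs <- utils::combn(present, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- fold_changes$fold_change[fold_changes$category == pr[1]]
    b <- fold_changes$fold_change[fold_changes$category == pr[2]]
    tibble::tibble(
      category_a = pr[1], category_b = pr[2],
      p_value = suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    )
  })
  list(summary = summary, tests = tests)
}
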