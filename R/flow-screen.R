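#' Normalize well fractions to the plate median
#'
#' Divides each well's fraction of fluorescent cells by the median fraction
#' of all wells on the same plate, removing plate-level batch effects. After
#' normalization the median `norm_value` of every plate is 1.
#'
#' @param measurements Tibble with at least `strain_id`, `plate_id`,
#'   `replicate`, `frac_positive`, `is_wt`; one row per well.
#' @return The input tibble with a `norm_value` column appended.
#' @examples
#' m <- tibble::tibble(strain_id = c("a", "b", "wt"), plate_id = "p1",
#'                     replicate = 1, frac_positive = c(0.02, 0.04, 0.06),
#'                     is_wt = c(FALSE, FALSE, TRUE))
#' plate_normalize(m)$norm_value
#' @export
plate_normalize <- function(measurements) {
  check_columns(measurements, c("strain_id", "plate_id", "frac_positive"),
                "measurements")
  if (any(measurements$frac_positive < 0 | measurements$frac_positive > 1, na.rm = TRUE))
    stop("frac_positive must lie in [0, 1]", call. = FALSE)
  counts <- dplyr::count(measurements, .data$plate_id)
  small <- counts$plate_id[counts$n < 3]
  if (length(small))
    stop("plates with fewer than 3 wells: ", paste(small, collapse = ", "),
         call. = FALSE)
  out <- measurements |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::mutate(.plate_median = stats::median(.data$frac_positive)) |>
    dplyr::ungroup()
  bad <- unique(out$plate_id[out$.plate_median <= 0])
  if (length(bad))
    stop("plate median is zero for plate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out |>
    dplyr::mutate(norm_value = .data$frac_positive / .data$.plate_median) |>
    dplyr::select(-".plate_median")
}

#' Prescreen strains exceeding a wild-type percentile in repeated replicates
#'
#' Flags strains whose plate-normalized value exceeds the given percentile
#' of the pooled wild-type normalized values in at least `min_reps` of their
#' replicates — the rule used to carry primary-screen candidates forward
#' (95th percentile in at least two of four replicates by default).
#'
#' @param normalized Output of [plate_normalize()] (needs `is_wt`).
#' @param percentile Wild-type percentile defining the threshold (0-100).
#' @param min_reps Minimum replicates above threshold for selection.
#' @param n_reps Expected replicates per strain; strains with more are
#'   rejected.
#' @return Character vector of selected strain ids.
#' @export
prescreen_hits <- function(normalized, percentile = 95, min_reps = 2, n_reps = 4) {
  check_columns(normalized, c("strain_id", "norm_value", "is_wt"), "normalized")
  stopifnot(percentile > 0, percentile < 100, min_reps >= 1)
  wt <- normalized$norm_value[normalized$is_wt]
  if (!length(wt)) stop("no wild-type measurements to define the threshold",
                        call. = FALSE)
  thr <- stats::quantile(wt, percentile / 100, names = FALSE, type = 7)
  muts <- dplyr::filter(normalized, !.data$is_wt)
  reps <- dplyr::count(muts, .data$strain_id)
  over <- reps$strain_id[reps$n > n_reps]
  if (length(over))
    stop("strains with more than n_reps replicates: ",
         paste(utils::head(over, 5), collapse = ", "), call. = FALSE)
  muts |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(n_above = sum(.data$norm_value > thr), .groups = "drop") |>
    dplyr::filter(.data$n_above >= min_reps) |>
    dplyr::pull("strain_id")
}

#' Partition pooled wild-type measurements into comparison groups
#'
#' Combines all wild-type normalized values and partitions them into
#' `n_groups` statistical comparison groups (ten by default) against which
#' individual mutant measurements are scored. When `by_batch = TRUE` the
#' partition follows the `batch` column (which must then define exactly
#' `n_groups` batches); otherwise a seeded random partition into groups of
#' near-equal size (differing by at most one) is drawn.
#'
#' @param wt_normalized Tibble of wild-type rows with `norm_value` (and
#'   `batch` when `by_batch`).
#' @param n_groups Number of comparison groups.
#' @param by_batch Use the `batch` column to define groups.
#' @param seed Seed for the random partition.
#' @return A list of class `comparison_groups`: `groups` (list of numeric
#'   vectors), `assignment` (integer group index per wild-type row), and
#'   `n_groups`.
#' @export
build_comparison_groups <- function(wt_normalized, n_groups = 10,
                                    by_batch = FALSE, seed = 1L) {
  check_columns(wt_normalized, "norm_value", "wt_normalized")
  n <- nrow(wt_normalized)
  if (n < n_groups)
    stop("n_groups (", n_groups, ") exceeds the number of wild-type measurements (",
         n, ")", call. = FALSE)
  if (by_batch) {
    check_columns(wt_normalized, "batch", "wt_normalized")
    batches <- unique(wt_normalized$batch)
    if (length(batches) != n_groups)
      stop("by_batch requires exactly n_groups batches; found ",
           length(batches), call. = FALSE)
    assignment <- match(wt_normalized$batch, batches)
  } else {
    withr::local_seed(as.integer(seed))
    assignment <- sample(rep_len(seq_len(n_groups), n))
  }
  groups <- split(wt_normalized$norm_value, assignment)
  names(groups) <- NULL
  structure(list(groups = groups, assignment = assignment, n_groups = n_groups),
            class = "comparison_groups")
}

#' @export
print.comparison_groups <- function(x, ...) {
  cat("<comparison_groups>", x$n_groups, "groups; sizes:",
      paste(lengths(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Recombination index of a measurement against a wild-type group
#'
#' The percentile-type screen statistic: the percentage of a pooled
#' wild-type comparison group lying below the measurement, with ties
#' counted at half weight (midranks). An index of 100 means every wild-type
#' value was lower (hyper-recombination end of the scale); 0 means every
#' wild-type value was higher (hypo-recombination).
#'
#' @param value Numeric vector of normalized measurements.
#' @param group Numeric vector: the wild-type comparison group.
#' @return Numeric vector of indices in \[0, 100\], one per `value`.
#' @examples
#' recombination_index(c(5, 0, 2.5), c(1, 2, 3, 4))
#' @export
recombination_index <- function(value, group) {
  if (!length(group)) stop("empty comparison group", call. = FALSE)
  stopifnot(is.numeric(value), is.numeric(group))
  vapply(value, function(v) {
    100 * (sum(group < v) + 0.5 * sum(group == v)) / length(group)
  }, numeric(1))
}

#' Score every strain of a normalized flow screen
#'
#' For each mutant strain: computes recombination indices of its normalized
#' measurements against its assigned comparison group, a two-sided
#' Mann-Whitney rank-sum p-value of its measurements against the pooled
#' wild-type values, and a direction call (`hyper` when the median index
#' exceeds 50 and p falls below `alpha`; `hypo` when below 50; `none`
#' otherwise). An optional Benjamini-Hochberg adjusted column is appended.
#'
#' @param normalized Output of [plate_normalize()].
#' @param groups A [build_comparison_groups()] result.
#' @param alpha Reporting threshold for the direction call.
#' @param seed Seed for the deterministic mutant-to-group assignment.
#' @return Tibble of class `flow_screen_result`, sorted by p-value:
#'   `strain_id`, `n`, `median_index`, `p_value`, `p_adj`, `direction`, and
#'   a list-column `indices` of per-measurement indices.
#' @export
score_strains <- function(normalized, groups, alpha = 0.05, seed = 1L) {
  check_columns(normalized, c("strain_id", "norm_value", "is_wt"), "normalized")
  stopifnot(inherits(groups, "comparison_groups"))
  wt_pool <- normalized$norm_value[normalized$is_wt]
  muts <- dplyr::filter(normalized, !.data$is_wt)
  strains <- unique(muts$strain_id)
  empty <- setdiff(strains, muts$strain_id[!is.na(muts$norm_value)])
  if (length(empty))
    warning("strains skipped with zero usable measurements: ",
            paste(empty, collapse = ", "))
  strains <- setdiff(strains, empty)

  withr::local_seed(as.integer(seed))
  grp_idx <- sample(rep_len(seq_len(groups$n_groups), length(strains)))
  names(grp_idx) <- strains

  res <- purrr::map_dfr(strains, function(s) {
    vals <- muts$norm_value[muts$strain_id == s & !is.na(muts$norm_value)]
    grp <- groups$groups[[grp_idx[[s]]]]
    idx <- recombination_index(vals, grp)
    p <- suppressWarnings(
      stats::wilcox.test(vals, wt_pool, alternative = "two.sided")$p.value
    )
    tibble::tibble(
      strain_id = s,
      n = length(vals),
      group = grp_idx[[s]],
      median_index = stats::median(idx),
      p_value = p,
      indices = list(idx)
    )
  })
  res <- res |>
    dplyr::mutate(
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      direction = dplyr::case_when(
        .data$p_value < alpha & .data$median_index > 50 ~ "hyper",
        .data$p_value < alpha & .data$median_index < 50 ~ "hypo",
        TRUE ~ "none"
      )
    ) |>
    dplyr::arrange(.data$p_value) |>
    dplyr::select("strain_id", "n", "group", "median_index", "p_value",
                  "p_adj", "direction", "indices")
  class(res) <- c("flow_screen_result", class(res))
  res
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(df)
}
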