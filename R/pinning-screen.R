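#' Call colonies positive from their size
#'
#' Marks each pinned position positive (recombinant, LEU+) when its colony
#' size reaches `size_threshold`; the boundary counts as positive.
#'
#' @param grids Tibble with `strain_id`, `selective_plate`, `colony_size`
#'   (and typically `row`, `col`, `growth_ok`).
#' @param size_threshold Required minimum colony size (same units as
#'   `colony_size`).
#' @return `grids` with a logical `positive` column appended.
#' @export
call_colonies <- function(grids, size_threshold) {
  check_columns(grids, c("strain_id", "colony_size"), "grids")
  stopifnot(is.numeric(size_threshold), length(size_threshold) == 1)
  if (any(grids$colony_size < 0, na.rm = TRUE))
    stop("negative colony_size encountered", call. = FALSE)
  message("calling colonies positive at size >= ", size_threshold)
  dplyr::mutate(grids, positive = .data$colony_size >= size_threshold)
}

#' Exclude strains that grew poorly before selection
#'
#' A strain is excluded when the fraction of its array positions flagged
#' `growth_ok` falls below `min_fraction`; excluded strains are never
#' scored, avoiding selection bias from poor growth on the pre-selection
#' media.
#'
#' @param grids Tibble with `strain_id` and `growth_ok`.
#' @param min_fraction Minimum fraction of positions with normal growth.
#' @return A list with `kept` and `excluded` character vectors of strain
#'   ids, plus `growth` (per-strain growth fractions).
#' @export
filter_growth <- function(grids, min_fraction = 0.75) {
  check_columns(grids, c("strain_id", "growth_ok"), "grids")
  growth <- grids |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(frac_ok = mean(.data$growth_ok), .groups = "drop")
  list(
    kept = growth$strain_id[growth$frac_ok >= min_fraction],
    excluded = growth$strain_id[growth$frac_ok < min_fraction],
    growth = growth
  )
}

#' Score a replica-pinning screen against pooled wild type
#'
#' Computes, per strain, the recombinant frequency over its colony calls
#' (48 under the standard 16-position x 3-plate design) and a two-sided
#' Fisher exact p-value on the 2x2 table of positive/negative calls versus
#' the pooled wild-type calls. Strains excluded by [filter_growth()] (or
#' with zero calls) are reported with `excluded = TRUE` and no p-value.
#'
#' @param grids Tibble of called colonies (after [call_colonies()]), with
#'   `positive` set; may include wild-type rows (`strain_id == wt_strain`),
#'   which are used as reference and not scored.
#' @param wt_calls Optional logical vector of pooled wild-type calls;
#'   defaults to the calls of `wt_strain` within `grids`.
#' @param wt_strain Strain id treated as wild type.
#' @param excluded Character vector of strains to exclude from scoring
#'   (e.g. `filter_growth()$excluded`).
#' @return Tibble of class `pinning_result`, sorted by p-value: `strain_id`,
#'   `n_calls`, `n_positive`, `frequency`, `p_value`, `excluded`.
#' @export
score_pinning <- function(grids, wt_calls = NULL, wt_strain = "wt",
                          excluded = character()) {
  check_columns(grids, c("strain_id", "positive"), "grids")
  if (is.null(wt_calls)) wt_calls <- grids$positive[grids$strain_id == wt_strain]
  if (!length(wt_calls)) stop("no wild-type calls to compare against", call. = FALSE)
  wt_pos <- sum(wt_calls)
  wt_neg <- length(wt_calls) - wt_pos

  per <- grids |>
    dplyr::filter(.data$strain_id != wt_strain) |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::summarise(n_calls = dplyr::n(), n_positive = sum(.data$positive),
                     .groups = "drop") |>
    dplyr::mutate(frequency = .data$n_positive / .data$n_calls,
                  excluded = .data$strain_id %in% .env$excluded)

  zero <- per$strain_id[per$n_calls == 0]
  if (length(zero)) warning("strains with zero calls excluded: ",
                            paste(zero, collapse = ", "))

  per$p_value <- purrr::pmap_dbl(
    per[c("n_positive", "n_calls", "excluded")],
    function(n_positive, n_calls, excluded) {
      if (excluded || n_calls == 0) return(NA_real_)
      stats::fisher.test(matrix(c(n_positive, n_calls - n_positive,
                                  wt_pos, wt_neg), nrow = 2))$p.value
    }
  )
  res <- dplyr::arrange(per, .data$excluded, .data$p_value)
  class(res) <- c("pinning_result", class(res))
  res
}
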