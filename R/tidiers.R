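#' Tidy a dot-blot standard curve
#'
#' @param x A [fit_standard()] result.
#' @param ... Unused.
#' @return Tibble with one row per curve parameter (`term`, `estimate`).
#' @export
tidy.dotblot_standard <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' Glance at a dot-blot standard curve
#'
#' @param x A [fit_standard()] result.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `n_points`, `n_used`.
#' @export
glance.dotblot_standard <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = length(x$used),
                 n_used = sum(x$used))
}

#' Tidy a flow screen result
#'
#' Drops the list-column of per-measurement indices, leaving one plain row
#' per strain.
#'
#' @param x A [score_strains()] result.
#' @param ... Unused.
#' @return Tibble of per-strain statistics.
#' @export
tidy.flow_screen_result <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -"indices")
  class(out) <- class(tibble::tibble())
  out
}

#' Glance at a flow screen result
#'
#' @param x A [score_strains()] result.
#' @param ... Unused.
#' @return One-row tibble: strain counts and direction tallies.
#' @export
glance.flow_screen_result <- function(x, ...) {
  tibble::tibble(
    n_strains = nrow(x),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    min_p = min(x$p_value)
  )
}
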