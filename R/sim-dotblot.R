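#' Simulate dot-blot dilution series
#'
#' Generates S9.6 and dsDNA channel intensities for a serial dilution of
#' each sample. Intensities are proportional to loaded amount times the
#' sample's planted hybrid level (S9.6 channel) or its DNA concentration
#' (dsDNA channel, equal across samples), with optional log-normal
#' measurement noise. The reference sample has level 1.
#'
#' @param seed Integer seed.
#' @param true_levels Named numeric vector of relative hybrid levels; a
#'   `"ref"` sample at level 1 is added if absent.
#' @param dilutions Decreasing relative DNA amounts loaded per spot.
#' @param noise_sd SD of log-normal intensity noise (0 = exact).
#' @return A list with class `dotblot_sim`: `series` (tibble `sample_id`,
#'   `channel`, `amount`, `intensity`) and `truth` (tibble `sample_id`,
#'   `relative_level`).
#' @export
sim_dotblot <- function(seed = 1L, true_levels = c(mutA = 3, mutB = 1.5),
                        dilutions = c(1, 0.5, 0.25, 0.125, 0.0625),
                        noise_sd = 0.05) {
  stopifnot(all(true_levels > 0), all(dilutions > 0), noise_sd >= 0)
  if (!"ref" %in% names(true_levels)) true_levels <- c(ref = 1, true_levels)
  withr::local_seed(as.integer(seed))
  k <- c(S9.6 = 1000, dsDNA = 2000)  # channel-specific exposure scales
  series <- tidyr::expand_grid(
    sample_id = names(true_levels),
    channel = c("S9.6", "dsDNA"),
    amount = dilutions
  ) |>
    dplyr::mutate(
      conc = ifelse(.data$channel == "S9.6",
                    true_levels[.data$sample_id], 1),
      intensity = k[.data$channel] * .data$conc * .data$amount *
        exp(stats::rnorm(dplyr::n(), 0, noise_sd))
    ) |>
    dplyr::select("sample_id", "channel", "amount", "intensity")
  structure(list(
    series = series,
    truth = tibble::tibble(sample_id = names(true_levels),
                           relative_level = unname(true_levels))
  ), class = "dotblot_sim")
}
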