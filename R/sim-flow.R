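#' Simulate a flow-cytometry recombination screen
#'
#' Draws per-well YFP-positive fractions for a plate-arrayed screen. Each
#' plate carries `n_wt_wells` wild-type wells plus mutant wells; every strain
#' is measured in `n_replicates` replicate plates. Fractions follow a
#' logit-normal model: `logit(p) = logit(wt_baseline) + plate effect +
#' log(fold) + well noise`, where the plate effect is shared by all wells of
#' a plate (a multiplicative effect on the odds) and `fold` is the planted
#' hyper-recombination fold-change for strains named in
#' `config$hyper_effects` (1 otherwise).
#'
#' @param config A [sim_config()].
#' @return A list with class `flow_sim`:
#' \describe{
#'   \item{measurements}{tibble with `strain_id`, `plate_id`, `well`,
#'     `replicate`, `frac_positive`, `is_wt` — one row per well.}
#'   \item{truth}{tibble with `strain_id`, `fold`, `is_hit` (fold > 1),
#'     the planted ground truth.}
#' }
#' @examples
#' sim <- sim_flow_screen(sim_config(seed = 1, n_strains = 12))
#' head(sim$measurements)
#' @export
sim_flow_screen <- function(config) {
  config <- validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, "flow"))

  strains <- sprintf("mut%03d", seq_len(config$n_strains))
  fold <- rep(1, config$n_strains)
  names(fold) <- strains
  planted <- intersect(names(config$hyper_effects), strains)
  extra <- setdiff(names(config$hyper_effects), strains)
  # effects named for strains outside the grid are appended as extra strains
  if (length(extra)) {
    strains <- c(strains, extra)
    fold <- c(fold, stats::setNames(rep(1, length(extra)), extra))
  }
  fold[names(config$hyper_effects)] <- config$hyper_effects

  mut_per_plate <- config$wells_per_plate - config$n_wt_wells
  n_plates <- ceiling(length(strains) / mut_per_plate)

  layout <- purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
    purrr::map_dfr(seq_len(n_plates), function(pl) {
      idx <- seq((pl - 1) * mut_per_plate + 1, min(pl * mut_per_plate, length(strains)))
      ids <- c(rep("wt", config$n_wt_wells), strains[idx])
      tibble::tibble(
        strain_id = ids,
        plate_id = sprintf("r%d_p%02d", rep_i, pl),
        well = seq_along(ids),
        replicate = rep_i,
        is_wt = ids == "wt"
      )
    })
  })

  plate_eff <- stats::rnorm(length(unique(layout$plate_id)), 0, config$plate_effect_sd)
  names(plate_eff) <- unique(layout$plate_id)
  base_logit <- stats::qlogis(config$wt_baseline)

  measurements <- layout |>
    dplyr::mutate(
      lp = base_logit + plate_eff[.data$plate_id] +
        log(ifelse(.data$is_wt, 1, fold[.data$strain_id])) +
        stats::rnorm(dplyr::n(), 0, config$well_sd),
      frac_positive = stats::plogis(.data$lp)
    ) |>
    dplyr::select("strain_id", "plate_id", "well", "replicate",
                  "frac_positive", "is_wt")

  fold_vec <- unname(fold[strains])
  truth <- tibble::tibble(
    strain_id = strains,
    fold = fold_vec,
    is_hit = fold_vec > 1
  )
  structure(list(measurements = measurements, truth = truth), class = "flow_sim")
}

#' Simulate a replica-pinning recombination screen
#'
#' Each strain occupies `pinning_positions` array positions on the source
#' plate; the array is pinned onto `pinning_plates` selective plates, so
#' every strain contributes `positions * plates` independent Bernoulli
#' colony calls (48 under the defaults). A positive call receives a colony
#' size drawn above the caller's default threshold; a negative call has size
#' 0. Strains listed in `config$growth_fail_strains` have their
#' pre-selection `growth_ok` flags set FALSE so the growth filter can be
#' exercised.
#'
#' @param config A [sim_config()].
#' @param strains Character vector of strain ids; defaults to the flow-screen
#'   strain set plus `"wt"`.
#' @return A list with class `pinning_sim`: `grids` (tibble of `strain_id`,
#'   `row`, `col`, `selective_plate`, `colony_size`, `growth_ok`) and
#'   `truth` (tibble of `strain_id`, `p_positive`, `growth_fail`).
#' @export
sim_pinning_screen <- function(config, strains = NULL) {
  config <- validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, "pinning"))
  if (is.null(strains)) {
    strains <- c("wt", sprintf("mut%03d", seq_len(config$n_strains)),
                 setdiff(names(config$pinning_effects), sprintf("mut%03d", seq_len(config$n_strains))))
    strains <- unique(strains)
  }

  p <- rep(config$pinning_p_wt, length(strains))
  names(p) <- strains
  known <- intersect(names(config$pinning_effects), strains)
  p[known] <- config$pinning_effects[known]

  side <- ceiling(sqrt(config$pinning_positions))
  pos <- tidyr::expand_grid(row = seq_len(side), col = seq_len(side))[
    seq_len(config$pinning_positions), ]

  grids <- tidyr::expand_grid(
    strain_id = strains,
    pos,
    selective_plate = seq_len(config$pinning_plates)
  ) |>
    dplyr::mutate(
      growth_ok = !(.data$strain_id %in% config$growth_fail_strains),
      positive_draw = stats::rbinom(dplyr::n(), 1L, p[.data$strain_id]) == 1L &
        .data$growth_ok,
      colony_size = ifelse(
        .data$positive_draw,
        config$colony_size_scale * stats::rlnorm(dplyr::n(), 0, 0.25),
        0
      )
    ) |>
    dplyr::select("strain_id", "row", "col", "selective_plate", "colony_size",
                  "growth_ok")

  truth <- tibble::tibble(
    strain_id = strains,
    p_positive = unname(p[strains]),
    growth_fail = strains %in% config$growth_fail_strains
  )
  structure(list(grids = grids, truth = truth), class = "pinning_sim")
}
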