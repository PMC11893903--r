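#' Run the full synthetic pipeline end to end
#'
#' Simulates every assay from one seeded configuration, runs each scoring
#' stage, and collects truth-recovery metrics into a single report:
#' flow screen (normalize, group, score; recall and false-positive rate on
#' planted hyper-recombinant strains), pinning screen (call, filter,
#' Fisher-score), dot-blot integration (standard curves, relative levels,
#' quartiles, level-recombination correlation), DRIP calibration (occupancy
#' ratios, per-gene densities, condition fold-change, RNase H sensitivity,
#' strand specificity), OK-seq orientation classification, and foci imaging
#' (segmentation, counting, proportion comparison). A fixed seed gives a
#' byte-identical JSON summary.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, stage tables are written
#'   as TSV and the summary as `summary.json`.
#' @param alpha Significance threshold used in the recovery metrics.
#' @return A list of class `pipeline_report`: per-stage result tables plus
#'   `summary` (the recovery metrics, a plain named list).
#' @export
run_pipeline <- function(config, out_dir = NULL, alpha = 0.05) {
  config <- validate_sim_config(config)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- flow screen -------------------------------------------------------
  flow <- stage("simulate-flow", sim_flow_screen(config))
  flow_scores <- stage("score-flow", {
    norm <- plate_normalize(flow$measurements)
    groups <- build_comparison_groups(dplyr::filter(norm, .data$is_wt),
                                      n_groups = min(10, sum(norm$is_wt)),
                                      seed = config$seed)
    score_strains(norm, groups, alpha = alpha, seed = config$seed)
  })
  flow_eval <- dplyr::left_join(flow_scores, flow$truth, by = "strain_id")
  hits <- flow_eval$is_hit
  flow_metrics <- list(
    n_strains = nrow(flow_eval),
    recall = if (any(hits)) mean(flow_eval$p_value[hits] < alpha &
                                   flow_eval$median_index[hits] > 50) else NA,
    false_positive_rate = if (any(!hits))
      mean(flow_eval$p_value[!hits] < alpha) else NA
  )

  ## -- pinning screen ----------------------------------------------------
  pin <- stage("simulate-pinning", sim_pinning_screen(config))
  pin_scores <- stage("score-pinning", {
    called <- suppressMessages(
      call_colonies(pin$grids, size_threshold = config$colony_size_scale / 4))
    growth <- filter_growth(called)
    score_pinning(called, excluded = growth$excluded)
  })
  pin_eval <- dplyr::left_join(pin_scores, pin$truth, by = "strain_id")
  planted <- pin_eval$p_positive > config$pinning_p_wt & !pin_eval$excluded
  pin_metrics <- list(
    calls_per_strain = unique(pin_eval$n_calls),
    planted_detected = if (any(planted))
      mean(pin_eval$p_value[planted] < alpha) else NA,
    wt_frequency = mean(pin$grids$colony_size[pin$grids$strain_id == "wt"] >=
                          config$colony_size_scale / 4)
  )

  ## -- dot-blot integration ---------------------------------------------
  blot <- stage("simulate-dotblot", sim_dotblot(
    seed = config$seed,
    true_levels = stats::setNames(
      exp(stats::qnorm(seq(0.1, 0.9, length.out = 8)) * 0.8),
      sprintf("mut%03d", 1:8))
  ))
  integration <- stage("integrate", {
    lv <- relative_level(blot$series, reference_id = "ref")
    lv_mut <- dplyr::filter(lv, .data$sample_id != "ref") |>
      dplyr::rename(strain_id = "sample_id")
    quart <- assign_quartiles(lv_mut)
    corr <- correlate_levels_recombination(
      lv_mut, flow_scores, metric_col = "median_index")
    list(levels = lv, quartiles = quart, correlation = corr)
  })
  level_err <- dplyr::inner_join(
    dplyr::rename(integration$levels, recovered = "relative_level"),
    blot$truth, by = "sample_id")
  blot_metrics <- list(
    max_level_rel_error = max(abs(level_err$recovered /
                                    level_err$relative_level - 1)),
    quartile_sizes = as.integer(table(integration$quartiles$quartile)),
    level_recombination_rho = integration$correlation$rho
  )

  ## -- DRIP --------------------------------------------------------------
  drip <- stage("simulate-drip", sim_drip_experiment(config))
  drip_out <- stage("drip-calibrate", calibrate_drip(drip$coverage,
                                                     drip$spike_counts))
  dens <- stage("drip-density", {
    drip_out$tracks |>
      dplyr::group_by(.data$sample_id, .data$condition, .data$treatment) |>
      dplyr::group_modify(function(df, key) gene_density(df, drip$genes)) |>
      dplyr::ungroup()
  })
  d_cm <- dplyr::filter(dens, .data$condition == "control",
                        .data$treatment == "mock")
  d_tm <- dplyr::filter(dens, .data$condition == "treated",
                        .data$treatment == "mock")
  d_cr <- dplyr::filter(dens, .data$condition == "control",
                        .data$treatment == "RNaseH")
  drip_metrics <- list(
    occupancy_ratios = stats::setNames(drip_out$ratios$occupancy_ratio,
                                       drip_out$ratios$sample_id),
    median_condition_fold = stats::median(density_fold_change(
      d_tm$template_density, d_cm$template_density)),
    median_rnh_sensitivity = stats::median(rnase_h_sensitivity(
      d_cm$template_density, d_cr$template_density), na.rm = TRUE),
    mean_template_specificity = mean(d_cm$specificity, na.rm = TRUE)
  )

  ## -- OK-seq orientation ------------------------------------------------
  ok <- stage("simulate-okseq", sim_okseq(config))
  ok_calls <- stage("classify-cdho", {
    withr::local_seed(stream_seed(config$seed, "groups"))
    win <- ok$truth |>
      dplyr::select("interval", "start", "end") |>
      dplyr::mutate(strand = sample(c("+", "-"), dplyr::n(), replace = TRUE))
    orientation_from_profile(ok$profile, win)
  })
  expected <- dplyr::case_when(
    ok_calls$fork_direction == "ambiguous" ~ NA_character_,
    (ok$truth$fork_direction == "right") == (ok_calls$strand == "+") ~ "CD",
    TRUE ~ "HO"
  )
  ok_metrics <- list(
    orientation_accuracy = mean(ok_calls$orientation == expected,
                                na.rm = TRUE),
    n_ambiguous = sum(ok_calls$orientation == "ambiguous")
  )

  ## -- foci imaging ------------------------------------------------------
  foci <- stage("simulate-foci", sim_foci_images(config))
  foci_records <- stage("count-foci", {
    purrr::imap_dfr(foci$stacks, function(st, img) {
      dplyr::mutate(analyze_stack(st), image = img, .before = 1)
    })
  })
  foci_eval <- match_nuclei(foci_records, foci$truth)
  half <- foci_eval$image <= max(1, config$n_images %/% 2)
  foci_metrics <- list(
    n_nuclei_found = nrow(foci_records),
    n_nuclei_planted = nrow(foci$truth),
    frac_exact = mean(foci_eval$foci_count == foci_eval$n_foci, na.rm = TRUE),
    frac_within_1 = mean(abs(foci_eval$foci_count - foci_eval$n_foci) <= 1,
                         na.rm = TRUE),
    null_group_fisher_p = if (any(half) && any(!half))
      compare_foci_proportions(foci_eval$foci_count[half],
                               foci_eval$foci_count[!half])$p_value else NA
  )

  summary <- list(
    seed = config$seed,
    flow = flow_metrics,
    pinning = pin_metrics,
    dotblot = blot_metrics,
    drip = drip_metrics,
    okseq = ok_metrics,
    foci = foci_metrics
  )

  report <- structure(list(
    flow_scores = flow_scores, pinning_scores = pin_scores,
    integration = integration, gene_densities = dens,
    orientation_calls = ok_calls, foci_records = foci_records,
    summary = summary
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(dplyr::select(flow_scores, -"indices"),
                     file.path(out_dir, "flow_scores.tsv"))
    readr::write_tsv(pin_scores, file.path(out_dir, "pinning_scores.tsv"))
    readr::write_tsv(dens, file.path(out_dir, "gene_densities.tsv"))
    readr::write_tsv(ok_calls, file.path(out_dir, "orientation_calls.tsv"))
    readr::write_tsv(foci_records, file.path(out_dir, "foci_records.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}

# match detected nuclei to planted truth by nearest mask centroid
match_nuclei <- function(records, truth) {
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cand <- records[records$image == tr$image, ]
    if (!nrow(cand)) return(dplyr::mutate(tr, foci_count = NA_integer_))
    d <- sqrt((cand$cx - tr$cx)^2 + (cand$cy - tr$cy)^2)
    j <- which.min(d)
    if (d[j] > tr$radius)
      return(dplyr::mutate(tr, foci_count = NA_integer_))
    dplyr::mutate(tr, foci_count = cand$foci_count[j])
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  s <- x$summary
  cat("  flow:  recall", signif(s$flow$recall, 3), " FPR",
      signif(s$flow$false_positive_rate, 3), "\n")
  cat("  drip:  fold", signif(s$drip$median_condition_fold, 3),
      " RNaseH sens.", signif(s$drip$median_rnh_sensitivity, 3),
      " specificity", signif(s$drip$mean_template_specificity, 3), "\n")
  cat("  okseq: accuracy", signif(s$okseq$orientation_accuracy, 3), "\n")
  cat("  foci:  exact", signif(s$foci$frac_exact, 3), " within 1",
      signif(s$foci$frac_within_1, 3), "\n")
  invisible(x)
}
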