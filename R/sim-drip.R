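#' Simulate a spike-in calibrated strand-specific DRIP experiment
#'
#' Generates binned strand-specific coverage for a synthetic experimental
#' genome plus spike-in read counts, for every sample of a two-condition
#' DRIP design: per condition (`control`, `treated`) an input library and
#' immunoprecipitated (IP) libraries with and without in vitro RNase H
#' digestion.
#'
#' The generative model: every gene contributes hybrid signal only on its
#' template strand (the C strand for a `+` gene, the W strand for a `-`
#' gene), at a density `txn_level * hybrid_per_txn` reads/bp, multiplied by
#' `condition_fold` in the treated condition and by `rnh_residual` under
#' RNase H. Both strands carry a uniform `background_density`. Input reads
#' follow DNA content, so the input spike-read fraction equals
#' `spike_fraction_input` (the 5 of the 95:5 cell mix). IP reads follow
#' hybrid mass; the spike-in genome's per-cell hybrid mass is held constant
#' across samples (the property that makes it a calibrant), so its IP read
#' share falls as the experimental genome gains hybrids. Bin counts are
#' Poisson draws around these expectations. A global IP capture efficiency
#' scales both genomes identically and therefore cancels from the occupancy
#' ratio.
#'
#' @param config A [sim_config()].
#' @return A list with class `drip_sim`:
#' \describe{
#'   \item{coverage}{tibble of binned IP/input coverage: `sample_id`,
#'     `condition`, `treatment`, `fraction`, `genome`, `strand` (W/C),
#'     `chrom`, `start`, `end` (0-based half-open), `count`.}
#'   \item{spike_counts}{tibble of `sample_id`, `condition`, `treatment`,
#'     `fraction`, `n_spike`, `n_total`.}
#'   \item{genes}{tibble of `gene_id`, `chrom`, `start`, `end`, `strand`,
#'     `txn_level`.}
#'   \item{truth}{tibble of per-gene planted hybrid densities
#'     (`hybrid_density`, reads/bp in excess of background) per condition
#'     and treatment, plus the `background_density`.}
#' }
#' @examples
#' sim <- sim_drip_experiment(sim_config(seed = 1, n_genes = 20,
#'                                       genome_length = 60000))
#' dplyr::count(sim$coverage, sample_id)
#' @export
sim_drip_experiment <- function(config) {
  config <- validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, "drip"))

  bw <- config$bin_width
  n_bins <- config$genome_length %/% bw
  chrom <- "chrSim"

  # genes tiled with even spacing, starts aligned to the bin grid
  spacing <- (config$genome_length %/% config$n_genes)
  gene_len <- min(config$gene_length, spacing - 2 * bw)
  starts <- (seq_len(config$n_genes) - 1L) * spacing + bw
  starts <- (starts %/% bw) * bw
  txn <- config$txn_levels %||% stats::rlnorm(config$n_genes, log(5), 0.5)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = chrom,
    start = starts,
    end = starts + gene_len,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    txn_level = txn
  )

  base_hybrid <- genes$txn_level * config$hybrid_per_txn
  samples <- tidyr::expand_grid(
    condition = c("control", "treated"),
    spec = tibble::tibble(
      fraction = c("input", "IP", "IP"),
      treatment = c("mock", "mock", "RNaseH")
    )
  ) |> tidyr::unnest("spec") |>
    dplyr::mutate(sample_id = paste(.data$condition, .data$fraction,
                                    .data$treatment, sep = "_"))

  truth <- tidyr::expand_grid(
    gene_id = genes$gene_id,
    condition = c("control", "treated"),
    treatment = c("mock", "RNaseH")
  ) |>
    dplyr::left_join(dplyr::select(genes, "gene_id", "txn_level"), by = "gene_id") |>
    dplyr::mutate(
      hybrid_density = .data$txn_level * config$hybrid_per_txn *
        ifelse(.data$condition == "treated", config$condition_fold, 1) *
        ifelse(.data$treatment == "RNaseH", config$rnh_residual, 1),
      background_density = config$background_density
    )

  # per-bp hybrid mass per strand for one experimental cell
  bin_starts <- (seq_len(n_bins) - 1L) * bw
  template_strand <- ifelse(genes$strand == "+", "C", "W")
  gene_bins <- purrr::map(seq_len(nrow(genes)), function(i) {
    seq(genes$start[i] %/% bw + 1L, (genes$end[i] - 1L) %/% bw + 1L)
  })

  strand_mass <- function(cond, treat) {
    # reads/bp expected on each strand, per bin
    mass <- list(W = rep(config$background_density, n_bins),
                 C = rep(config$background_density, n_bins))
    mult <- ifelse(cond == "treated", config$condition_fold, 1) *
      ifelse(treat == "RNaseH", config$rnh_residual, 1)
    for (i in seq_len(nrow(genes))) {
      s <- template_strand[i]
      mass[[s]][gene_bins[[i]]] <- mass[[s]][gene_bins[[i]]] + base_hybrid[i] * mult
    }
    mass
  }

  # spike per-cell hybrid mass: fixed at the control/mock experimental value
  mass_total <- function(mass) (sum(mass$W) + sum(mass$C)) * bw
  h_spike <- mass_total(strand_mass("control", "mock"))
  cell_exp <- 1 - config$spike_fraction_input
  cell_spike <- config$spike_fraction_input

  cov_list <- list()
  spike_list <- list()
  for (k in seq_len(nrow(samples))) {
    smp <- samples[k, ]
    if (smp$fraction == "input") {
      f_spike <- config$spike_fraction_input
      n_spike <- stats::rbinom(1L, size = as.integer(config$seq_depth), prob = f_spike)
      depth_exp <- config$seq_depth - n_spike
      lambda <- rep(depth_exp / (2 * n_bins), 2 * n_bins)
    } else {
      mass <- strand_mass(smp$condition, smp$treatment)
      h_exp <- mass_total(mass)
      f_spike <- (cell_spike * h_spike) /
        (cell_spike * h_spike + cell_exp * h_exp)
      n_spike <- stats::rbinom(1L, size = as.integer(config$seq_depth), prob = f_spike)
      depth_exp <- config$seq_depth - n_spike
      w <- c(mass$W, mass$C) * bw
      lambda <- depth_exp * w / sum(w)
    }
    counts <- stats::rpois(2L * n_bins, lambda)
    cov_list[[k]] <- tibble::tibble(
      sample_id = smp$sample_id,
      condition = smp$condition,
      treatment = smp$treatment,
      fraction = smp$fraction,
      genome = "experimental",
      strand = rep(c("W", "C"), each = n_bins),
      chrom = chrom,
      start = rep(bin_starts, 2L),
      end = rep(bin_starts + bw, 2L),
      count = counts
    )
    spike_list[[k]] <- tibble::tibble(
      sample_id = smp$sample_id,
      condition = smp$condition,
      treatment = smp$treatment,
      fraction = smp$fraction,
      n_spike = n_spike,
      n_total = as.integer(config$seq_depth)
    )
  }

  structure(list(
    coverage = dplyr::bind_rows(cov_list),
    spike_counts = dplyr::bind_rows(spike_list),
    genes = genes,
    truth = truth
  ), class = "drip_sim")
}

#' Simulate an OK-seq replication-direction profile
#'
#' Produces a piecewise-linear signal along one chromosome: each of
#' `okseq_n_intervals` segments receives a slope of known sign and magnitude
#' (`okseq_slope`, in signal units per kb; occasional zero-slope segments
#' are planted as ambiguous), sampled at
#' `okseq_points_per_interval` evenly spaced positions with Gaussian noise
#' `okseq_noise_sd` added.
#'
#' @param config A [sim_config()].
#' @param zero_fraction Fraction of intervals planted with slope 0
#'   (truth direction "ambiguous").
#' @return A list with class `okseq_sim`: `profile` (tibble `chrom`,
#'   `position`, `signal`) and `truth` (tibble `interval`, `start`, `end`,
#'   `slope_per_kb`, `fork_direction` under the convention that a positive
#'   slope means a rightward-moving fork).
#' @export
sim_okseq <- function(config, zero_fraction = 0) {
  config <- validate_sim_config(config)
  stopifnot(zero_fraction >= 0, zero_fraction <= 1)
  withr::local_seed(stream_seed(config$seed, "okseq"))

  n <- config$okseq_n_intervals
  slopes <- sample(c(-1, 1), n, replace = TRUE) * config$okseq_slope
  n_zero <- round(zero_fraction * n)
  if (n_zero > 0) slopes[sample.int(n, n_zero)] <- 0

  len <- config$okseq_interval_bp
  truth <- tibble::tibble(
    interval = seq_len(n),
    start = (seq_len(n) - 1) * len,
    end = seq_len(n) * len,
    slope_per_kb = slopes,
    fork_direction = dplyr::case_when(
      slopes > 0 ~ "right",
      slopes < 0 ~ "left",
      TRUE ~ "ambiguous"
    )
  )

  profile <- purrr::map_dfr(seq_len(n), function(i) {
    pos <- seq(truth$start[i], truth$end[i],
               length.out = config$okseq_points_per_interval)
    mid <- (truth$start[i] + truth$end[i]) / 2
    tibble::tibble(
      chrom = "chrSim",
      interval = i,
      position = pos,
      signal = slopes[i] * (pos - mid) / 1000 +
        stats::rnorm(length(pos), 0, config$okseq_noise_sd)
    )
  })

  structure(list(profile = profile, truth = truth), class = "okseq_sim")
}
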