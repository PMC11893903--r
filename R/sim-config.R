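#' Simulation configuration for synthetic screen and genomics data
#'
#' Builds the single seeded configuration object consumed by every generator
#' in the package ([sim_flow_screen()], [sim_pinning_screen()],
#' [sim_drip_experiment()], [sim_okseq()], [sim_foci_images()]). Defaults
#' describe the study conditions the scoring functions were designed for:
#' a genome-wide flow-cytometry recombination screen read out as per-well
#' YFP-positive fractions, a 16-position x 3-plate replica-pinning screen,
#' a spike-in calibrated strand-specific DRIP experiment with a hybrid-rich
#' calibration genome mixed at a 95:5 cell ratio, piecewise-linear OK-seq
#' replication-direction profiles, and z-stack images of nuclei carrying
#' repair foci.
#'
#' Fractions of fluorescent cells are simulated on a logit-normal scale so
#' that multiplicative plate effects and strain fold-changes act on the odds
#' while values stay inside \[0, 1\].
#'
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce byte-identical outputs from every generator.
#' @param n_strains Number of mutant strains in the flow screen.
#' @param n_wt_wells Number of wild-type control wells per plate.
#' @param wells_per_plate Wells per assay plate (wild-type plus mutants).
#' @param n_replicates Replicate measurements per strain (replicate plates).
#' @param wt_baseline Mean wild-type YFP-positive fraction.
#' @param plate_effect_sd SD of the per-plate multiplicative effect on the
#'   odds scale (log units), shared by all wells of a plate.
#' @param well_sd Well-to-well SD on the logit scale. The wild-type
#'   well-to-well spread is not a published quantity, so it is exposed here
#'   rather than hard-coded.
#' @param hyper_effects Named numeric vector mapping strain id to the
#'   fold-change applied to its recombination odds (values > 1 plant
#'   hyper-recombination; unnamed strains are null).
#' @param pinning_p_wt Wild-type probability that one pinned position gives a
#'   LEU+ colony.
#' @param pinning_effects Named numeric vector mapping strain id to its LEU+
#'   probability (overrides `pinning_p_wt`).
#' @param pinning_positions Array positions per strain on the source plate.
#' @param pinning_plates Selective plates each position is pinned onto;
#'   positions x plates gives the calls per strain (16 x 3 = 48 by default).
#' @param growth_fail_strains Character vector of strains planted as poor
#'   growers (their `growth_ok` flags are set FALSE).
#' @param colony_size_scale Mean size of a positive colony, in the arbitrary
#'   units the colony caller thresholds on.
#' @param n_genes Number of genes on the synthetic experimental genome.
#' @param genome_length Length of the experimental genome in bp.
#' @param bin_width Coverage bin width in bp.
#' @param gene_length Gene body length in bp.
#' @param txn_levels Optional numeric vector (length `n_genes`) of
#'   transcription levels; drawn log-normally when `NULL`.
#' @param hybrid_per_txn Template-strand hybrid density contributed per unit
#'   of transcription (reads/bp in truth units).
#' @param background_density Background density on both strands (reads/bp).
#' @param spike_fraction_input Fraction of input-library reads mapping to the
#'   spike-in genome (the 5 in 95:5).
#' @param ip_efficiency Global immunoprecipitation capture efficiency; scales
#'   IP yield for both genomes equally and therefore cancels in the
#'   occupancy ratio.
#' @param condition_fold Hybrid fold-change planted in the treated condition.
#' @param rnh_residual Fraction of hybrid signal surviving in vitro RNase H
#'   treatment (0 = complete digestion).
#' @param seq_depth Total mapped reads per sequenced sample.
#' @param okseq_n_intervals Number of piecewise-linear OK-seq segments.
#' @param okseq_interval_bp Length of each OK-seq segment in bp.
#' @param okseq_points_per_interval Signal points sampled per segment.
#' @param okseq_slope Magnitude of the planted OK-seq slope (signal per kb).
#' @param okseq_noise_sd SD of Gaussian noise added to the OK-seq signal.
#' @param image_size Side length (pixels) of each synthetic image.
#' @param n_images Number of image stacks per condition.
#' @param n_nuclei Nuclei per image.
#' @param nucleus_radius Nucleus radius in pixels.
#' @param n_z Number of z slices in the foci channel.
#' @param foci_per_nucleus Integer vector recycled over nuclei giving planted
#'   focus counts.
#' @param foci_snr Peak signal-to-noise ratio of a planted focus over the
#'   Poisson background.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_strains = 24)
#' cfg$wt_baseline
#' @export
sim_config <- function(seed = 1L,
                       n_strains = 96L,
                       n_wt_wells = 8L,
                       wells_per_plate = 96L,
                       n_replicates = 4L,
                       wt_baseline = 0.01,
                       plate_effect_sd = 0.2,
                       well_sd = 0.25,
                       hyper_effects = c(hpr1 = 8, mft1 = 6, rad27 = 5),
                       pinning_p_wt = 0.02,
                       pinning_effects = c(mft1 = 0.3, rad27 = 0.2),
                       pinning_positions = 16L,
                       pinning_plates = 3L,
                       growth_fail_strains = character(),
                       colony_size_scale = 1,
                       n_genes = 200L,
                       genome_length = 600000L,
                       bin_width = 20L,
                       gene_length = 1500L,
                       txn_levels = NULL,
                       hybrid_per_txn = 0.04,
                       background_density = 0.005,
                       spike_fraction_input = 0.05,
                       ip_efficiency = 1,
                       condition_fold = 2,
                       rnh_residual = 0.1,
                       seq_depth = 2e6,
                       okseq_n_intervals = 40L,
                       okseq_interval_bp = 15000L,
                       okseq_points_per_interval = 15L,
                       okseq_slope = 1,
                       okseq_noise_sd = 0.5,
                       image_size = 256L,
                       n_images = 4L,
                       n_nuclei = 12L,
                       nucleus_radius = 14,
                       n_z = 5L,
                       foci_per_nucleus = c(0L, 1L, 2L, 3L),
                       foci_snr = 10) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  cat("  flow:    ", x$n_strains, "strains x", x$n_replicates, "replicates, baseline",
      x$wt_baseline, "\n")
  cat("  pinning: ", x$pinning_positions, "positions x", x$pinning_plates,
      "plates =", x$pinning_positions * x$pinning_plates, "calls/strain\n")
  cat("  drip:    ", x$n_genes, "genes /", x$genome_length, "bp, condition fold",
      x$condition_fold, ", RNase H residual", x$rnh_residual, "\n")
  cat("  imaging: ", x$n_images, "stacks x", x$n_nuclei, "nuclei, SNR", x$foci_snr, "\n")
  invisible(x)
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid sim_config field `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(cfg, field) {
  v <- cfg[[field]]
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v))
    fail_field(field, "must be a single integer >= 1")
}

check_fraction <- function(cfg, field) {
  v <- cfg[[field]]
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
    fail_field(field, "must be a fraction in [0, 1]")
}

check_positive <- function(cfg, field, strict = TRUE) {
  v <- cfg[[field]]
  ok <- is.numeric(v) && length(v) == 1 && !is.na(v) && (if (strict) v > 0 else v >= 0)
  if (!ok) fail_field(field, if (strict) "must be a positive number" else "must be >= 0")
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (f in c("n_strains", "n_wt_wells", "wells_per_plate", "n_replicates",
              "pinning_positions", "pinning_plates", "n_genes", "genome_length",
              "bin_width", "gene_length", "okseq_n_intervals", "okseq_interval_bp",
              "okseq_points_per_interval", "image_size", "n_images", "n_nuclei",
              "n_z")) {
    check_count(cfg, f)
  }
  for (f in c("wt_baseline", "pinning_p_wt", "spike_fraction_input", "rnh_residual")) {
    check_fraction(cfg, f)
  }
  for (f in c("plate_effect_sd", "well_sd", "colony_size_scale", "hybrid_per_txn",
              "condition_fold", "ip_efficiency", "seq_depth", "okseq_slope",
              "nucleus_radius", "foci_snr")) {
    check_positive(cfg, f)
  }
  for (f in c("background_density", "okseq_noise_sd")) check_positive(cfg, f, strict = FALSE)
  if (length(cfg$hyper_effects) &&
      (!is.numeric(cfg$hyper_effects) || is.null(names(cfg$hyper_effects)) ||
       any(cfg$hyper_effects <= 0)))
    fail_field("hyper_effects", "must be a named numeric vector of fold-changes > 0")
  if (length(cfg$pinning_effects) &&
      (!is.numeric(cfg$pinning_effects) || is.null(names(cfg$pinning_effects)) ||
       any(cfg$pinning_effects < 0) || any(cfg$pinning_effects > 1)))
    fail_field("pinning_effects", "must be a named numeric vector of probabilities")
  if (!is.null(cfg$txn_levels) &&
      (!is.numeric(cfg$txn_levels) || length(cfg$txn_levels) != cfg$n_genes ||
       any(cfg$txn_levels < 0)))
    fail_field("txn_levels", "must be NULL or non-negative with one value per gene")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    fail_field("seed", "must be a single integer")
  if (cfg$n_wt_wells + 1 > cfg$wells_per_plate)
    fail_field("n_wt_wells", "must leave at least one mutant well per plate")
  if (!is.numeric(cfg$foci_per_nucleus) || any(cfg$foci_per_nucleus < 0))
    fail_field("foci_per_nucleus", "must be non-negative counts")
  cfg
}

# Derive a stream-specific seed from the master seed so that generators are
# independent of each other yet jointly reproducible. Kept below 2^31.
stream_seed <- function(seed, stream) {
  offsets <- c(flow = 101L, pinning = 211L, drip = 307L, okseq = 401L,
               foci = 503L, groups = 601L)
  (as.integer(seed) * 7919L + offsets[[stream]]) %% 2147483647L
}
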