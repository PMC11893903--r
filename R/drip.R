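#' Spike-in occupancy ratio
#'
#' The calibration factor for one IP sample: the spike-in genome's read
#' fraction in the input library divided by its read fraction in the IP
#' library. When the experimental genome gains hybrids the spike-in's IP
#' share falls and the ratio rises, so multiplying IP coverage by it makes
#' tracks comparable across samples. The ratio is invariant to sequencing
#' depth and to any global change of IP efficiency that affects both
#' genomes equally.
#'
#' @param input,ip One-row data frames (or lists) with `n_spike` and
#'   `n_total` read counts for the input and IP libraries of one sample.
#' @return A positive scalar.
#' @examples
#' occupancy_ratio(list(n_spike = 5000, n_total = 1e5),
#'                 list(n_spike = 1000, n_total = 1e5))
#' @export
occupancy_ratio <- function(input, ip) {
  for (x in list(input, ip)) {
    if (is.null(x$n_spike) || is.null(x$n_total))
      stop("input and ip need n_spike and n_total", call. = FALSE)
    if (x$n_spike <= 0)
      stop("zero spike-in reads: sequence (or simulate) deeper to calibrate",
           call. = FALSE)
    if (x$n_spike > x$n_total) stop("n_spike exceeds n_total", call. = FALSE)
  }
  (input$n_spike / input$n_total) / (ip$n_spike / ip$n_total)
}

#' Calibrate a binned IP coverage track
#'
#' Scales raw IP bin counts to calibrated units:
#' `count * 1e6 / ip_total * or_value`. Only experimental-genome bins are
#' calibrated (spike-in bins, if present, are dropped). The result is
#' invariant to uniform depth rescaling of the sample and proportional to
#' true occupancy.
#'
#' @param ip_coverage Tibble of IP bins with a `count` column (and
#'   optionally a `genome` column, filtered to `"experimental"`).
#' @param or_value Occupancy ratio from [occupancy_ratio()].
#' @param ip_total Total mapped reads of the IP library.
#' @return The coverage tibble with a `calibrated` column.
#' @export
calibrate <- function(ip_coverage, or_value, ip_total) {
  check_columns(ip_coverage, "count", "ip_coverage")
  if (!is.numeric(or_value) || or_value <= 0)
    stop("or_value must be positive", call. = FALSE)
  if (ip_total <= 0) stop("ip_total must be positive", call. = FALSE)
  if ("genome" %in% names(ip_coverage))
    ip_coverage <- dplyr::filter(ip_coverage, .data$genome == "experimental")
  dplyr::mutate(ip_coverage,
                calibrated = .data$count * 1e6 / ip_total * or_value)
}

#' Calibrate every IP sample of a DRIP experiment
#'
#' Convenience wrapper pairing each IP library with its condition's input
#' library, computing the occupancy ratio from the spike-in counts, and
#' calibrating the IP coverage.
#'
#' @param coverage Coverage tibble as produced by [sim_drip_experiment()]
#'   (columns `sample_id`, `condition`, `treatment`, `fraction`, `strand`,
#'   `chrom`, `start`, `end`, `count`).
#' @param spike_counts Spike-in count tibble (`sample_id`, `condition`,
#'   `fraction`, `n_spike`, `n_total`).
#' @return A list: `tracks` (calibrated IP coverage tibble) and `ratios`
#'   (per-sample occupancy ratios).
#' @export
calibrate_drip <- function(coverage, spike_counts) {
  check_columns(coverage, c("sample_id", "condition", "fraction", "count"),
                "coverage")
  check_columns(spike_counts, c("sample_id", "condition", "fraction",
                                "n_spike", "n_total"), "spike_counts")
  ip_samples <- dplyr::filter(spike_counts, .data$fraction == "IP")
  ratios <- purrr::map_dfr(seq_len(nrow(ip_samples)), function(i) {
    ip <- ip_samples[i, ]
    inp <- dplyr::filter(spike_counts, .data$condition == ip$condition,
                         .data$fraction == "input")
    if (nrow(inp) != 1)
      stop("expected exactly one input sample for condition ", ip$condition,
           call. = FALSE)
    tibble::tibble(sample_id = ip$sample_id,
                   occupancy_ratio = occupancy_ratio(inp, ip),
                   ip_total = ip$n_total)
  })
  tracks <- coverage |>
    dplyr::filter(.data$fraction == "IP") |>
    dplyr::inner_join(ratios, by = "sample_id") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      calibrate(df, df$occupancy_ratio[1], df$ip_total[1])
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-"occupancy_ratio", -"ip_total")
  list(tracks = tracks, ratios = ratios)
}

# template strand of a + gene is C (the strand the nascent RNA anneals to);
# of a - gene, W
template_strand_of <- function(gene_strand) ifelse(gene_strand == "+", "C", "W")

#' Per-gene template and non-template hybrid densities
#'
#' Mean calibrated signal per bp over each gene body, computed separately
#' for the gene's template strand (C for a `+` gene, W for a `-` gene) and
#' non-template strand. Bins partially overlapping a gene edge contribute
#' in proportion to their overlap. Specificity is
#' `template / (template + nontemplate)`.
#'
#' @param track Calibrated coverage tibble for one sample with `strand`,
#'   `chrom`, `start`, `end` and the value column.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param value_col Column of `track` holding the signal (default
#'   `"calibrated"`).
#' @return Tibble `gene_id`, `template_density`, `nontemplate_density`,
#'   `specificity`.
#' @export
gene_density <- function(track, genes, value_col = "calibrated") {
  check_columns(track, c("strand", "chrom", "start", "end", value_col), "track")
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  absent <- setdiff(genes$chrom, track$chrom)
  if (length(absent))
    stop("gene chromosome(s) absent from track: ",
         paste(unique(absent), collapse = ", "), call. = FALSE)

  strand_density <- function(strand_label) {
    sub <- dplyr::filter(track, .data$strand == strand_label)
    bins <- GenomicRanges::GRanges(sub$chrom,
                                   IRanges::IRanges(sub$start + 1, sub$end))
    g <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1, genes$end))
    hits <- GenomicRanges::findOverlaps(g, bins)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(g)[S4Vectors::queryHits(hits)],
      IRanges::ranges(bins)[S4Vectors::subjectHits(hits)]
    ))
    bw <- sub$end - sub$start
    # reads attributed to the gene from each bin, assuming uniformity in-bin
    reads <- sub[[value_col]][S4Vectors::subjectHits(hits)] *
      ov / bw[S4Vectors::subjectHits(hits)]
    dens <- rep(0, nrow(genes))
    agg <- tapply(reads, S4Vectors::queryHits(hits), sum)
    dens[as.integer(names(agg))] <- agg
    dens / (genes$end - genes$start)
  }

  dens <- list(W = strand_density("W"), C = strand_density("C"))
  tmpl <- template_strand_of(genes$strand)
  template_density <- ifelse(tmpl == "C", dens$C, dens$W)
  nontemplate_density <- ifelse(tmpl == "C", dens$W, dens$C)
  tot <- template_density + nontemplate_density
  tibble::tibble(
    gene_id = genes$gene_id,
    template_density = template_density,
    nontemplate_density = nontemplate_density,
    specificity = ifelse(tot > 0, template_density / tot, NA_real_)
  )
}

#' RNase H sensitivity of a hybrid density
#'
#' Fractional loss of signal after in vitro RNase H digestion:
#' `1 - density_rnh / density_mock`. A value of 1 means complete digestion;
#' 0 means no sensitivity. Undefined (NA, with a warning) where the mock
#' density is zero.
#'
#' @param density_mock,density_rnh Numeric vectors of matched densities.
#' @return Numeric vector of sensitivities (<= 1).
#' @export
rnase_h_sensitivity <- function(density_mock, density_rnh) {
  out <- 1 - density_rnh / density_mock
  bad <- density_mock == 0
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad), " mock densities are zero; sensitivity undefined there")
    out[bad] <- NA_real_
  }
  out
}

#' Hybrid density fold-change between conditions
#'
#' `(treated + pseudocount) / (control + pseudocount)`; the pseudocount
#' regularises zero densities (0/0 maps to 1).
#'
#' @param density_treated,density_control Numeric vectors.
#' @param pseudocount Small positive stabiliser.
#' @return Numeric vector of fold-changes.
#' @export
density_fold_change <- function(density_treated, density_control,
                                pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  if (any(c(density_treated, density_control) < 0, na.rm = TRUE))
    stop("densities must be >= 0", call. = FALSE)
  (density_treated + pseudocount) / (density_control + pseudocount)
}

#' TSS-TES metagene matrices for template and non-template strands
#'
#' Builds one row per gene: `flank_bp` of unscaled coverage bins upstream
#' of the TSS, the gene body resampled to `body_bins` columns, and
#' `flank_bp` of unscaled bins downstream of the TES. Rows are oriented 5'
#' to 3' of the gene (minus-strand genes are reversed) and sorted by
#' template-strand gene density, highest first. Two matrices are returned:
#' one for each gene's template strand and one for its non-template strand.
#'
#' @param track Calibrated coverage tibble for one sample (uniform bin
#'   width required).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param flank_bp Unscaled flank on each side (multiple of the bin width).
#' @param body_bins Number of columns the gene body is rescaled to.
#' @param value_col Signal column of `track`.
#' @return Object of class `metagene_matrix`: list with `template` and
#'   `nontemplate` matrices (rows = genes, in `row_order`), `flank_bins`,
#'   `body_bins`.
#' @export
metagene <- function(track, genes, flank_bp = 500, body_bins = 50,
                     value_col = "calibrated") {
  check_columns(track, c("strand", "chrom", "start", "end", value_col), "track")
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  bw <- unique(track$end - track$start)
  if (length(bw) != 1)
    stop("metagene requires a uniform bin width", call. = FALSE)
  flank_bins <- ceiling(flank_bp / bw)

  # per (chrom, strand) lookup of bin index -> value
  lookup <- track |>
    dplyr::mutate(bin = .data$start %/% bw) |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_split()
  key <- vapply(lookup, function(d) paste(d$chrom[1], d$strand[1]), character(1))
  names(lookup) <- key

  bin_values <- function(chrom, strand_label, from_bin, to_bin) {
    d <- lookup[[paste(chrom, strand_label)]]
    idx <- match(seq(from_bin, to_bin), d$bin)
    vals <- d[[value_col]][idx]
    vals[is.na(vals)] <- 0
    vals
  }

  short <- genes$end - genes$start < bw
  if (any(short))
    warning(sum(short), " gene(s) shorter than one bin; body resampled from",
            " a single bin value")

  one_row <- function(i, which_strand) {
    g <- genes[i, ]
    strand_label <- if (which_strand == "template") template_strand_of(g$strand)
      else setdiff(c("W", "C"), template_strand_of(g$strand))
    b0 <- g$start %/% bw
    b1 <- (g$end - 1) %/% bw
    up <- bin_values(g$chrom, strand_label, b0 - flank_bins, b0 - 1)
    body <- bin_values(g$chrom, strand_label, b0, b1)
    down <- bin_values(g$chrom, strand_label, b1 + 1, b1 + flank_bins)
    if (length(body) == 1) {
      body_rs <- rep(body, body_bins)
    } else {
      body_rs <- stats::approx(seq_along(body), body,
                               xout = seq(1, length(body),
                                          length.out = body_bins))$y
    }
    row <- c(up, body_rs, down)
    if (g$strand == "-") row <- rev(row)
    row
  }

  dens <- gene_density(track, genes, value_col = value_col)
  ord <- order(-dens$template_density)
  mk <- function(which_strand) {
    m <- t(vapply(ord, one_row, numeric(2 * flank_bins + body_bins),
                  which_strand = which_strand))
    rownames(m) <- genes$gene_id[ord]
    m
  }
  structure(list(
    template = mk("template"),
    nontemplate = mk("nontemplate"),
    row_order = genes$gene_id[ord],
    flank_bins = flank_bins,
    body_bins = body_bins,
    bin_width = bw
  ), class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("<metagene_matrix>", nrow(x$template), "genes x",
      ncol(x$template), "columns (", x$flank_bins, "flank +", x$body_bins,
      "body +", x$flank_bins, "flank bins )\n")
  invisible(x)
}

#' OK-seq signal slope over a window
#'
#' Ordinary least-squares slope of the replication-direction proxy signal
#' versus genomic position over a window; the slope sign encodes the
#' predominant fork direction under a stated convention.
#'
#' @param profile Tibble with `position` and `signal`.
#' @param window Length-2 numeric `c(start, end)`; half-open on bp.
#' @return Tibble with `slope_per_kb`, `slope_se_per_kb`, `n`, `r_squared`.
#' @export
okseq_slope <- function(profile, window = NULL) {
  check_columns(profile, c("position", "signal"), "profile")
  sub <- profile
  if (!is.null(window))
    sub <- dplyr::filter(profile, .data$position >= window[1],
                         .data$position < window[2])
  if (nrow(sub) < 3)
    stop("need at least 3 points in the window; got ", nrow(sub), call. = FALSE)
  fit <- stats::lm(signal ~ I(position / 1000), data = sub)
  sm <- suppressWarnings(summary(fit))
  tibble::tibble(
    slope_per_kb = unname(stats::coef(fit)[2]),
    slope_se_per_kb = sm$coefficients[2, 2],
    n = nrow(sub),
    r_squared = sm$r.squared
  )
}

#' Classify gene orientation relative to the replication fork
#'
#' Converts an OK-seq slope into a fork direction under the chosen sign
#' convention (ambiguous when `|slope| < k * slope_se`) and crosses it with
#' the gene's transcription strand: co-directional (CD) when fork and
#' transcription point the same way, head-on (HO) otherwise.
#'
#' @param slope,slope_se Numeric vectors (per gene/window).
#' @param gene_strand Character vector of `"+"`/`"-"`.
#' @param sign_convention `"positive_slope_means_rightward"` (default) or
#'   `"positive_slope_means_leftward"`; the polarity of public OK-seq
#'   datasets varies, so this is an explicit parameter.
#' @param k Ambiguity band: calls with `|slope| < k * slope_se` are
#'   ambiguous (default 2, avoiding coin-flip calls at flat signal).
#' @return Tibble `fork_direction` (right/left/ambiguous) and `orientation`
#'   (CD/HO/ambiguous).
#' @export
classify_orientation <- function(slope, slope_se, gene_strand,
                                 sign_convention = c(
                                   "positive_slope_means_rightward",
                                   "positive_slope_means_leftward"),
                                 k = 2) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(all(gene_strand %in% c("+", "-")))
  n <- max(length(slope), length(gene_strand))
  slope <- rep_len(slope, n); slope_se <- rep_len(slope_se, n)
  gene_strand <- rep_len(gene_strand, n)
  s <- if (sign_convention == "positive_slope_means_rightward") slope else -slope
  fork <- dplyr::case_when(
    abs(slope) < k * slope_se | slope == 0 ~ "ambiguous",
    s > 0 ~ "right",
    TRUE ~ "left"
  )
  orientation <- dplyr::case_when(
    fork == "ambiguous" ~ "ambiguous",
    (fork == "right") == (gene_strand == "+") ~ "CD",
    TRUE ~ "HO"
  )
  tibble::tibble(fork_direction = fork, orientation = orientation)
}

#' Orientation calls for a set of windows on an OK-seq profile
#'
#' Fits [okseq_slope()] in each window and classifies orientation with
#' [classify_orientation()].
#'
#' @param profile OK-seq tibble (`position`, `signal`).
#' @param windows Tibble with `start`, `end`, a `strand` column of
#'   transcription directions, and an id column (first column used).
#' @param ... Passed to [classify_orientation()].
#' @return `windows` with `slope_per_kb`, `slope_se_per_kb`,
#'   `fork_direction`, `orientation` appended.
#' @export
orientation_from_profile <- function(profile, windows, ...) {
  check_columns(windows, c("start", "end", "strand"), "windows")
  fits <- purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    okseq_slope(profile, window = c(windows$start[i], windows$end[i]))
  })
  calls <- classify_orientation(fits$slope_per_kb, fits$slope_se_per_kb,
                                windows$strand, ...)
  dplyr::bind_cols(windows, fits[c("slope_per_kb", "slope_se_per_kb")], calls)
}

#' Percent of input immunoprecipitated from qPCR cycle thresholds
#'
#' `%IP = 100 * input_fraction * efficiency^(ct_input - ct_ip)`: with the
#' standard 5% input aliquot and perfect doubling, equal cycle thresholds
#' mean 5% of the locus was captured.
#'
#' @param qpcr Tibble with `ct_input`, `ct_ip` and optionally
#'   `input_fraction` (default filled with `input_fraction` argument).
#' @param input_fraction Fraction of the reaction taken as input aliquot.
#' @param efficiency Per-cycle amplification factor, in (1, 2].
#' @return `qpcr` with a `percent_ip` column.
#' @export
qpcr_percent_ip <- function(qpcr, input_fraction = 0.05, efficiency = 2.0) {
  check_columns(qpcr, c("ct_input", "ct_ip"), "qpcr")
  if (!(efficiency > 1 && efficiency <= 2))
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  stopifnot(all(is.finite(qpcr$ct_input)), all(is.finite(qpcr$ct_ip)))
  if (!"input_fraction" %in% names(qpcr))
    qpcr$input_fraction <- input_fraction
  if (any(qpcr$input_fraction <= 0 | qpcr$input_fraction > 1))
    stop("input_fraction must lie in (0, 1]", call. = FALSE)
  dplyr::mutate(qpcr, percent_ip = 100 * .data$input_fraction *
                  efficiency^(.data$ct_input - .data$ct_ip))
}

#' Adjust locus %IP to a synthetic spike-in
#'
#' Normalizes each locus' percent of input to the percent of input measured
#' for the synthetic hybrid spike-in:
#' `adjusted = percent_ip * reference_spike / percent_ip_spike`. Global
#' changes in IP efficiency scale locus and spike identically and cancel.
#'
#' @param percent_ip Numeric vector of locus %IP values.
#' @param percent_ip_spike Positive scalar (or vector) %IP of the spike-in.
#' @param reference_spike Adjusted value assigned to the spike-in itself.
#' @return Numeric vector of adjusted %IP.
#' @export
qpcr_adjust <- function(percent_ip, percent_ip_spike, reference_spike = 100) {
  if (any(percent_ip_spike <= 0))
    stop("spike-in percent IP must be positive", call. = FALSE)
  percent_ip * reference_spike / percent_ip_spike
}
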