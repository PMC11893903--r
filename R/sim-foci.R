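#' Simulate image stacks of nuclei with repair foci
#'
#' Generates, per image, a 2D DAPI channel containing disk-shaped
#' non-overlapping nuclei and a 3D focus channel (z-stack) in which each
#' nucleus carries a planted number of point sources (Gaussian spots spread
#' across z slices). Pixel values are Poisson draws around the expected
#' image; with `noiseless = TRUE` the expectation itself is returned. The
#' focus amplitude is `foci_snr` times the Poisson noise SD of the focus
#' channel background.
#'
#' @param config A [sim_config()].
#' @param noiseless If TRUE, skip Poisson noise (exact expected images).
#' @return A list with class `foci_sim`:
#' \describe{
#'   \item{stacks}{list of length `n_images`; each element has `dapi`
#'     (matrix) and `foci` (array x-y-z).}
#'   \item{truth}{tibble `image`, `nucleus_id`, `cx`, `cy`, `radius`,
#'     `n_foci`.}
#'   \item{foci_truth}{tibble of planted focus coordinates
#'     (`image`, `nucleus_id`, `x`, `y`, `z`).}
#' }
#' @export
sim_foci_images <- function(config, noiseless = FALSE) {
  config <- validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, "foci"))

  S <- config$image_size
  r <- config$nucleus_radius
  bg_dapi <- 2
  amp_dapi <- 60
  bg_foci <- 10
  amp_foci <- config$foci_snr * sqrt(bg_foci)
  spot_sigma <- 1.2
  min_focus_sep <- 7

  xs <- matrix(rep(seq_len(S), S), nrow = S)
  ys <- t(xs)

  place_centers <- function(n) {
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < n && tries < 20000) {
      cand <- stats::runif(2, min = r + 3, max = S - r - 3)
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * r + 6)) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1
    }
    if (nrow(centers) < n)
      stop("could not place ", n, " non-overlapping nuclei; reduce n_nuclei or nucleus_radius")
    centers
  }

  stacks <- vector("list", config$n_images)
  truth <- list()
  foci_truth <- list()
  foci_counts <- rep(as.integer(config$foci_per_nucleus),
                     length.out = config$n_nuclei)

  for (img in seq_len(config$n_images)) {
    centers <- place_centers(config$n_nuclei)
    dapi_exp <- matrix(bg_dapi, S, S)
    foci_exp <- array(bg_foci, dim = c(S, S, config$n_z))
    counts <- sample(foci_counts)  # shuffle counts over nuclei

    for (k in seq_len(config$n_nuclei)) {
      cx <- centers[k, 1]; cy <- centers[k, 2]
      disk <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      dapi_exp[disk] <- bg_dapi + amp_dapi
      truth[[length(truth) + 1]] <- tibble::tibble(
        image = img, nucleus_id = k, cx = cx, cy = cy, radius = r,
        n_foci = counts[k]
      )
      if (counts[k] == 0) next
      # rejection-sample focus positions: inside the nucleus, separated
      pts <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (nrow(pts) < counts[k] && tries < 5000) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * (r - 4)
        cand <- c(cx + rad * cos(ang), cy + rad * sin(ang))
        if (nrow(pts) == 0 ||
            all(sqrt(rowSums(sweep(pts, 2, cand)^2)) > min_focus_sep)) {
          pts <- rbind(pts, cand)
        }
        tries <- tries + 1
      }
      if (nrow(pts) < counts[k])
        stop("could not place ", counts[k], " separated foci in one nucleus")
      for (j in seq_len(nrow(pts))) {
        z <- sample.int(config$n_z, 1)
        fx <- pts[j, 1]; fy <- pts[j, 2]
        box <- 5L
        ix <- max(1, round(fx) - box):min(S, round(fx) + box)
        iy <- max(1, round(fy) - box):min(S, round(fy) + box)
        spot <- amp_foci * exp(-((outer(ix, rep(1, length(iy))) - fx)^2 +
                                 (outer(rep(1, length(ix)), iy) - fy)^2) /
                                 (2 * spot_sigma^2))
        foci_exp[ix, iy, z] <- foci_exp[ix, iy, z] + spot
        foci_truth[[length(foci_truth) + 1]] <- tibble::tibble(
          image = img, nucleus_id = k, x = fx, y = fy, z = z
        )
      }
    }

    if (noiseless) {
      stacks[[img]] <- list(dapi = dapi_exp, foci = foci_exp)
    } else {
      dapi_obs <- matrix(stats::rpois(S * S, dapi_exp), S, S)
      foci_obs <- array(stats::rpois(length(foci_exp), foci_exp),
                        dim = dim(foci_exp))
      stacks[[img]] <- list(dapi = dapi_obs, foci = foci_obs)
    }
  }

  structure(list(
    stacks = stacks,
    truth = dplyr::bind_rows(truth),
    foci_truth = if (length(foci_truth)) dplyr::bind_rows(foci_truth) else
      tibble::tibble(image = integer(), nucleus_id = integer(),
                     x = numeric(), y = numeric(), z = integer())
  ), class = "foci_sim")
}
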