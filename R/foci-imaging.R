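#' Maximum-intensity projection of an image stack
#'
#' Pixelwise maximum over the z dimension of a 3D array; a 2D matrix is
#' returned unchanged (a single-slice stack).
#'
#' @param stack 2D matrix or 3D array (x, y, z).
#' @return 2D matrix.
#' @export
max_project <- function(stack) {
  if (is.null(dim(stack)) || length(stack) == 0)
    stop("empty image stack", call. = FALSE)
  if (length(dim(stack)) == 2) return(stack)
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("stack must be a 2D matrix or x-y-z array with >= 1 slice",
         call. = FALSE)
  apply(stack, c(1, 2), max)
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, global Otsu threshold, connected-component
#' labelling, and removal of components smaller than `min_area` pixels.
#' A constant image yields zero nuclei with a warning.
#'
#' @param dapi 2D matrix of DAPI intensities.
#' @param sigma Gaussian smoothing SD in pixels.
#' @param min_area Minimum component area in pixels.
#' @return Integer label matrix (0 = background, 1..n = nuclei), with
#'   labels renumbered consecutively.
#' @export
segment_nuclei <- function(dapi, sigma = 2, min_area = 50) {
  stopifnot(is.matrix(dapi))
  rng <- range(dapi)
  if (diff(rng) == 0) {
    warning("constant DAPI image: no nuclei segmented")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  norm <- (dapi - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  lab <- EBImage::bwlabel(EBImage::Image(sm > thr))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  relab <- integer(max(lab) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  matrix(relab[lab + 1L], nrow(lab), ncol(lab))
}

#' Count foci per nucleus as local maxima in a projection
#'
#' Detects foci in a (maximum-intensity projected) signal image as local
#' maxima separated by at least `min_distance` pixels, with intensity
#' exceeding the nucleus background (median intensity inside the nucleus)
#' by `prominence` times the image's signal scale (image maximum minus
#' image median). Prominence is therefore relative: counts are invariant
#' to uniform intensity rescaling. Maxima falling outside every nucleus
#' are discarded; plateaus of equal-valued maxima count once.
#'
#' @param projection 2D signal matrix (see [max_project()]).
#' @param mask Integer nucleus label matrix from [segment_nuclei()].
#' @param min_distance Minimum separation between counted maxima (pixels).
#' @param prominence Fraction of the image signal scale a focus must rise
#'   above its nucleus background.
#' @param smooth_sigma Gaussian smoothing applied before detection
#'   (0 disables).
#' @return Tibble `nucleus_id`, `foci_count` (one row per labelled
#'   nucleus, including zero counts).
#' @export
count_foci <- function(projection, mask, min_distance = 5, prominence = 0.5,
                       smooth_sigma = 1) {
  stopifnot(is.matrix(projection), is.matrix(mask),
            all(dim(projection) == dim(mask)))
  n_nuc <- max(mask)
  counts <- tibble::tibble(nucleus_id = seq_len(n_nuc), foci_count = 0L)
  if (n_nuc == 0) return(counts[0, ])

  img <- projection
  if (smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(projection),
                                    sigma = smooth_sigma))
  scale_ref <- max(img) - stats::median(img)
  if (scale_ref <= 0) return(counts)

  brush <- EBImage::makeBrush(2 * ceiling(min_distance) + 1, shape = "disc")
  maxfilt <- as.matrix(EBImage::dilate(EBImage::Image(img), brush))

  nuc_bg <- vapply(seq_len(n_nuc), function(k) stats::median(img[mask == k]),
                   numeric(1))
  thr_img <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(n_nuc))
    thr_img[mask == k] <- nuc_bg[k] + prominence * scale_ref

  cand <- img >= maxfilt & img > thr_img & mask > 0
  if (!any(cand)) return(counts)
  comp <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand))))
  for (cc in seq_len(max(comp))) {
    idx <- which(comp == cc, arr.ind = TRUE)
    centroid <- round(colMeans(idx))
    nuc <- mask[centroid[1], centroid[2]]
    if (nuc == 0) nuc <- mask[idx[1, 1], idx[1, 2]]
    if (nuc > 0)
      counts$foci_count[nuc] <- counts$foci_count[nuc] + 1L
  }
  counts
}

#' Mean intensity of each labelled nucleus
#'
#' @param image 2D intensity matrix.
#' @param mask Integer nucleus label matrix.
#' @return Tibble `nucleus_id`, `area`, `cx`, `cy` (mask centroid),
#'   `mean_intensity`.
#' @export
nuclear_intensity <- function(image, mask) {
  stopifnot(is.matrix(image), is.matrix(mask), all(dim(image) == dim(mask)))
  n_nuc <- max(mask)
  if (n_nuc == 0)
    return(tibble::tibble(nucleus_id = integer(), area = integer(),
                          cx = numeric(), cy = numeric(),
                          mean_intensity = numeric()))
  purrr::map_dfr(seq_len(n_nuc), function(k) {
    idx <- which(mask == k, arr.ind = TRUE)
    tibble::tibble(
      nucleus_id = k,
      area = nrow(idx),
      cx = mean(idx[, 1]),
      cy = mean(idx[, 2]),
      mean_intensity = mean(image[mask == k])
    )
  })
}

#' Segment, project and count foci for one image stack
#'
#' Convenience wrapper producing per-nucleus records from a DAPI channel
#' and a focus-channel z-stack.
#'
#' @param stack List with `dapi` (matrix) and `foci` (matrix or x-y-z
#'   array), as produced by [sim_foci_images()].
#' @param sigma,min_area Passed to [segment_nuclei()].
#' @param min_distance,prominence,smooth_sigma Passed to [count_foci()].
#' @return Tibble `nucleus_id`, `area`, `mean_intensity` (focus channel),
#'   `foci_count`.
#' @export
analyze_stack <- function(stack, sigma = 2, min_area = 50, min_distance = 5,
                          prominence = 0.5, smooth_sigma = 1) {
  stopifnot(is.list(stack), !is.null(stack$dapi), !is.null(stack$foci))
  mask <- segment_nuclei(stack$dapi, sigma = sigma, min_area = min_area)
  proj <- max_project(stack$foci)
  dplyr::left_join(
    nuclear_intensity(proj, mask),
    count_foci(proj, mask, min_distance = min_distance,
               prominence = prominence, smooth_sigma = smooth_sigma),
    by = "nucleus_id"
  )
}

#' Compare proportions of foci-containing cells between two groups
#'
#' Builds the 2x2 table of cells with at least `positive_threshold` foci
#' versus fewer, by condition, and applies a two-sided Fisher exact test.
#'
#' @param counts_a,counts_b Integer vectors of per-cell focus counts.
#' @param positive_threshold Minimum foci for a cell to count as
#'   focus-containing.
#' @return Tibble `prop_a`, `prop_b`, `n_a`, `n_b`, `p_value`.
#' @export
compare_foci_proportions <- function(counts_a, counts_b,
                                     positive_threshold = 1) {
  stopifnot(length(counts_a) > 0, length(counts_b) > 0)
  pos_a <- sum(counts_a >= positive_threshold)
  pos_b <- sum(counts_b >= positive_threshold)
  tab <- matrix(c(pos_a, length(counts_a) - pos_a,
                  pos_b, length(counts_b) - pos_b), nrow = 2)
  tibble::tibble(
    prop_a = pos_a / length(counts_a),
    prop_b = pos_b / length(counts_b),
    n_a = length(counts_a),
    n_b = length(counts_b),
    p_value = stats::fisher.test(tab)$p.value
  )
}
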