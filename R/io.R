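#' Read a bedGraph coverage track
#'
#' Parses a 4-column bedGraph (track lines allowed) into a tibble of
#' 0-based half-open bins, validating that bins are sorted and
#' non-overlapping. Strand, genome, sample and fraction identity are not
#' part of the format; supply them via `...` (recycled metadata columns),
#' typically from the file-naming manifest.
#'
#' @param path bedGraph file.
#' @param ... Named metadata columns to attach (e.g. `strand = "W"`,
#'   `sample_id = "control_IP_mock"`).
#' @return Tibble `chrom`, `start`, `end`, `count` plus metadata columns.
#' @export
read_bedgraph <- function(path, ...) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) {
    warning("empty bedGraph: ", path)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), count = numeric(), ...))
  }
  df <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    count = gr$score
  )
  # per chromosome: sorted, non-overlapping
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$start))
      stop("unsorted intervals on ", ch, " near record ",
           which(df$chrom == ch)[which(diff(sub$start) < 0)[1] + 1],
           " of ", path, call. = FALSE)
    ov <- which(sub$start[-1] < sub$end[-nrow(sub)])
    if (length(ov))
      stop("overlapping intervals on ", ch, " at record ",
           which(df$chrom == ch)[ov[1] + 1], " of ", path, call. = FALSE)
    gaps <- sub$start[-1] - sub$end[-nrow(sub)]
    if (nrow(sub) >= 3 && all(gaps == 1) && sub$start[1] >= 1)
      stop("intervals in ", path, " look 1-based inclusive (uniform 1-bp ",
           "gaps between consecutive bins); bedGraph must be 0-based ",
           "half-open", call. = FALSE)
  }
  dplyr::mutate(df, ...)
}

#' Write a coverage track as bedGraph
#'
#' Writes `chrom`, `start`, `end` and one value column as 0-based
#' half-open bedGraph.
#'
#' @param track Tibble with `chrom`, `start`, `end` and `value_col`.
#' @param path Output file.
#' @param value_col Column written as the bedGraph score.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "count") {
  check_columns(track, c("chrom", "start", "end", value_col), "track")
  readr::write_tsv(track[, c("chrom", "start", "end", value_col)], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Returns genes as 0-based half-open intervals regardless of the input
#' convention (GFF3's 1-based inclusive coordinates are converted). Strand
#' is mandatory; duplicated gene ids are an error. A BED score column, or a
#' GFF3 score, is carried as `txn_level` when present.
#'
#' @param path `.bed` or `.gff`/`.gff3` file (format inferred from the
#'   extension, overridable with `format`).
#' @param format `"bed"` or `"gff3"`.
#' @param feature_type For GFF3, which `type` to keep (default `"gene"`;
#'   NULL keeps everything).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `txn_level`.
#' @export
read_genes <- function(path, format = NULL, feature_type = "gene") {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3" && !is.null(feature_type) && "type" %in%
      names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature_type]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("strand is mandatory for gene models; found unstranded records in ",
         path, call. = FALSE)
  ids <- if (!is.null(gr$Name) && !all(is.na(gr$Name))) as.character(gr$Name)
    else if (!is.null(gr$ID)) as.character(gr$ID)
    else if (!is.null(gr$name)) as.character(gr$name)
    else paste0("gene", seq_along(gr))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  score <- if ("score" %in% names(S4Vectors::mcols(gr)))
    as.numeric(gr$score) else NA_real_
  tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = strand,
    txn_level = score
  )
}

#' Write gene models as BED6
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) and optionally `txn_level` (written to the score
#'   column).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  check_columns(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  score <- if ("txn_level" %in% names(genes)) genes$txn_level else 0
  bed <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                        end = genes$end, name = genes$gene_id,
                        score = score, strand = genes$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a table of flow-cytometry well measurements
#'
#' TSV with columns `strain_id`, `plate_id`, `replicate`, `frac_positive`
#' and `is_wt`; validated on read.
#'
#' @param path TSV file.
#' @return Tibble of measurements.
#' @export
read_flow_measurements <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("strain_id", "plate_id", "replicate", "frac_positive",
                      "is_wt"), path)
  if (any(df$frac_positive < 0 | df$frac_positive > 1))
    stop("frac_positive outside [0, 1] in ", path, call. = FALSE)
  keys <- intersect(c("strain_id", "plate_id", "replicate", "well"), names(df))
  if (anyDuplicated(df[keys]))
    stop("duplicated (strain, plate, replicate) rows in ", path, call. = FALSE)
  df
}

#' Read a table of replica-pinning colony calls
#'
#' TSV with columns `strain_id`, `row`, `col`, `selective_plate`,
#' `colony_size`, `growth_ok`.
#'
#' @param path TSV file.
#' @return Tibble of grid records.
#' @export
read_pinning_grids <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("strain_id", "row", "col", "selective_plate",
                      "colony_size", "growth_ok"), path)
  if (any(df$colony_size < 0))
    stop("negative colony_size in ", path, call. = FALSE)
  df
}

#' Write and read image stacks as 16-bit multi-page TIFF
#'
#' Intensities are stored as 16-bit grayscale: values are divided by
#' `max_value` on write and multiplied back on read, so integer photon
#' counts up to `max_value` round-trip exactly.
#'
#' @param stack List with `dapi` (matrix) and `foci` (matrix or array).
#' @param dapi_path,foci_path Output TIFF paths.
#' @param max_value Intensity mapped to the 16-bit maximum.
#' @return The paths, invisibly.
#' @export
write_image_stack <- function(stack, dapi_path, foci_path, max_value = 65535) {
  stopifnot(max(stack$dapi) <= max_value, max(stack$foci) <= max_value)
  tiff::writeTIFF(stack$dapi / max_value, dapi_path, bits.per.sample = 16)
  foci <- stack$foci
  if (length(dim(foci)) == 2) foci <- array(foci, dim = c(dim(foci), 1))
  slices <- lapply(seq_len(dim(foci)[3]), function(z) foci[, , z] / max_value)
  tiff::writeTIFF(slices, foci_path, bits.per.sample = 16)
  invisible(c(dapi_path, foci_path))
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dapi_path, foci_path, max_value = 65535) {
  dapi <- tiff::readTIFF(dapi_path) * max_value
  slices <- tiff::readTIFF(foci_path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  foci <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (z in seq_along(slices)) foci[, , z] <- slices[[z]] * max_value
  list(dapi = round(dapi), foci = round(foci))
}
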