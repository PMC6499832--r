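# Core domain containers.
#
# Tabular objects (TAD sets, conformations) are plain tibbles with a small
# class tag so dplyr verbs keep working on them; square objects (contact
# maps, FISH distance matrices) are base matrices with a class tag, the
# natural container for symmetric pairwise data.

#' Construct a contact map
#'
#' A contact map is a symmetric, non-negative matrix of interaction
#' frequencies between genomic bins (or between whole TADs at TAD-level
#' resolution).  Values may be raw or pre-normalised counts: the embedding
#' normalises them to neighbour affinities internally, which is
#' scale-invariant.
#'
#' @param mat A square numeric matrix; symmetrised by `(M + t(M))/2`.
#' @param resolution Bin width in bp, or the string `"tad"` for TAD-level
#'   maps.
#' @return A `contact_map` (numeric matrix with zero diagonal).
#' @export
contact_map <- function(mat, resolution = "tad") {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("contact map must be square")
  if (any(!is.finite(mat))) abort("contact map entries must be finite")
  if (any(mat < 0)) abort("contact map entries must be non-negative")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  dimnames(mat) <- NULL
  structure(mat, resolution = resolution, class = c("contact_map", "matrix"))
}

#' Construct a FISH mean-distance matrix
#'
#' Mean pairwise spatial distances between TADs, in micrometres, as
#' measured by multiplexed FISH imaging averaged over cells.  `NA` entries
#' mark TAD pairs without a measurement; they are excluded from the FISH
#' restraint term and from relative-error averaging, never imputed.
#'
#' @param mat A square numeric matrix (µm).  Asymmetric input is averaged
#'   with a warning.
#' @return A `fish_dist` matrix with zero diagonal.
#' @export
fish_dist <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) abort("FISH distance matrix must be square")
  asym <- suppressWarnings(max(abs(mat - t(mat)), na.rm = TRUE))
  if (is.finite(asym) && asym > 1e-9 * max(1, max(abs(mat), na.rm = TRUE))) {
    warn("asymmetric FISH matrix: entries averaged with their transpose")
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  if (any(mat < 0, na.rm = TRUE)) abort("FISH distances must be positive")
  if (any(mat[row(mat) != col(mat)] == 0, na.rm = TRUE)) {
    abort("off-diagonal FISH distances must be > 0 (use NA for missing)")
  }
  dimnames(mat) <- NULL
  structure(mat, class = c("fish_dist", "matrix"))
}

#' Construct a TAD set
#'
#' An ordered set of non-overlapping genomic intervals (BED convention:
#' 0-based start, exclusive end) on a single chromosome, one row per TAD.
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end Interval bounds in bp (0-based, half-open).
#' @return A tibble with columns `tad`, `chrom`, `start`, `end`.
#' @export
tad_set <- function(chrom, start, end) {
  df <- tibble(chrom = chrom, start = as.numeric(start),
               end = as.numeric(end))
  if (nrow(df) == 0) abort("empty TAD set")
  if (length(unique(df$chrom)) != 1) {
    abort("a TAD set must lie on a single chromosome")
  }
  if (any(df$start >= df$end)) abort("TAD intervals need start < end")
  df <- arrange(df, .data$start)
  if (any(df$start[-1] < df$end[-nrow(df)])) {
    abort("TAD intervals must not overlap")
  }
  mutate(df, tad = seq_len(nrow(df)), .before = 1)
}

#' Construct a conformation
#'
#' An ordered set of 3D points (µm), one per genomic bin or per TAD, with
#' locus metadata.  Conformations are ordinary tibbles so they pipe through
#' dplyr; `coords_matrix()` extracts the raw coordinates.
#'
#' @param xyz n x 3 coordinate matrix (µm).
#' @param bins Optional tibble of locus metadata with columns among
#'   `chrom`, `start`, `end`, `tad`; must have n rows.
#' @return A tibble with columns `index`, optional metadata, `x`, `y`, `z`.
#' @export
conformation <- function(xyz, bins = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) abort("coordinates must be n x 3")
  if (any(!is.finite(xyz))) abort("coordinates must be finite")
  out <- tibble(index = seq_len(nrow(xyz)))
  if (!is.null(bins)) {
    bins <- as_tibble(bins)
    if (nrow(bins) != nrow(xyz)) {
      abort("metadata rows must match the number of points")
    }
    keep <- intersect(c("chrom", "start", "end", "tad"), names(bins))
    out <- dplyr::bind_cols(out, bins[, keep])
  }
  out$x <- xyz[, 1]
  out$y <- xyz[, 2]
  out$z <- xyz[, 3]
  out
}

# Replace the coordinates of a conformation, keeping metadata.
set_coords <- function(conf, xyz) {
  conf$x <- xyz[, 1]
  conf$y <- xyz[, 2]
  conf$z <- xyz[, 3]
  conf
}

#' First and last points of each TAD in a conformation
#'
#' @param conf A conformation tibble with a `tad` column.
#' @return A tibble with one row per TAD: `tad`, `first_index`,
#'   `last_index`.
#' @export
tad_endpoints <- function(conf) {
  stopifnot("tad" %in% names(conf))
  conf |>
    mutate(.row = seq_len(dplyr::n())) |>
    group_by(.data$tad) |>
    summarise(first_index = min(.data$.row), last_index = max(.data$.row),
              .groups = "drop") |>
    arrange(.data$tad)
}

# Genomic centre-to-centre distances (bp) between all TAD pairs.
tad_genomic_separation <- function(tads) {
  centres <- (tads$start + tads$end) / 2
  abs(outer(centres, centres, `-`))
}
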