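# Readers and writers for the external text formats: dense/triplet contact
# matrices, BED TAD intervals, CSV FISH distance tables, CSV and
# pseudo-atom PDB conformations.

#' Read a contact map from a text file
#'
#' @param path File path.
#' @param format `"dense"` for a whitespace- or comma-separated square
#'   matrix, `"triplet"` for 3-column `i j value` rows with 0-based
#'   indices.
#' @param n For triplet input, the matrix dimension; inferred from the
#'   largest index when omitted.
#' @param bins Optional TAD set (or any data frame with one row per
#'   matrix row): the loaded matrix must match its dimension.
#' @param resolution Passed to [contact_map()].
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path, format = c("dense", "triplet"), n = NULL,
                             bins = NULL, resolution = "tad") {
  format <- match.arg(format)
  if (!is.null(bins) && is.null(n)) n <- nrow(bins)
  if (format == "dense") {
    mat <- as.matrix(read_numeric_table(path))
  } else {
    trip <- read_numeric_table(path)
    if (ncol(trip) != 3) abort("triplet input needs 3 columns: i j value")
    i <- as.integer(trip[[1]]) + 1L
    j <- as.integer(trip[[2]]) + 1L
    v <- trip[[3]]
    if (any(i < 1) || any(j < 1)) abort("triplet indices must be >= 0")
    dim_n <- if (is.null(n)) max(i, j) else n
    mat <- matrix(0, dim_n, dim_n)
    mat[cbind(i, j)] <- v
    mat[cbind(j, i)] <- v
  }
  if (!is.null(bins) && nrow(mat) != nrow(bins)) {
    abort(sprintf("contact map dimension %d does not match %d bins",
                  nrow(mat), nrow(bins)))
  }
  contact_map(mat, resolution = resolution)
}

#' Write a contact map as a dense matrix file
#' @param map A `contact_map`.
#' @param path Output path.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(unclass(map), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read TAD intervals from a BED file
#'
#' Uses the standard BED convention (0-based, half-open).  Rows are sorted
#' by start; overlapping intervals are rejected.
#'
#' @param path BED file with at least 3 columns.
#' @return A TAD set tibble (see [tad_set()]).
#' @export
read_tads <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) abort("empty BED file")
  tad_set(chrom = as.character(GenomeInfoDb::seqnames(gr)),
          start = BiocGenerics::start(gr) - 1L,
          end = BiocGenerics::end(gr))
}

#' Write TAD intervals to a BED file
#' @param tads A TAD set tibble.
#' @param path Output path.
#' @export
write_tads <- function(tads, path) {
  readr::write_tsv(tads[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a FISH mean-distance matrix from CSV
#'
#' @param path CSV with a square numeric table (header row of TAD
#'   ordinals is accepted and ignored).  Empty cells or `NA` mark missing
#'   measurements.
#' @return A `fish_dist` matrix.
#' @export
read_fish_matrix <- function(path) {
  df <- read_numeric_table(path)
  fish_dist(as.matrix(df))
}

#' Write a FISH distance matrix to CSV
#' @param fish A `fish_dist` matrix.
#' @param path Output path.
#' @export
write_fish_matrix <- function(fish, path) {
  utils::write.csv(unclass(fish), path, row.names = FALSE)
  invisible(path)
}

#' Write a conformation to CSV or pseudo-atom PDB
#'
#' The CSV layout is one row per point with columns `index`, any locus
#' metadata, and `x`, `y`, `z` (µm).  The PDB layout writes one pseudo-atom
#' per point (CA atoms), one chain per TAD, consecutive points linked by
#' CONECT records; coordinates are rescaled when they would overflow the
#' fixed-width PDB coordinate field, with the scale factor recorded in a
#' REMARK header.
#'
#' @param conf A conformation tibble.
#' @param path Output path.
#' @param format `"csv"` or `"pdb"`.
#' @export
write_conformation <- function(conf, path, format = c("csv", "pdb")) {
  format <- match.arg(format)
  if (any(!is.finite(coords_matrix(conf)))) {
    abort("conformation has non-finite coordinates")
  }
  if (format == "csv") {
    readr::write_csv(conf, path)
  } else {
    write_conformation_pdb(conf, path)
  }
  invisible(path)
}

#' Read a conformation written by [write_conformation()] (CSV)
#' @param path CSV path.
#' @return A conformation tibble.
#' @export
read_conformation <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df
}

write_conformation_pdb <- function(conf, path) {
  xyz <- coords_matrix(conf)
  # PDB coordinate fields are %8.3f: rescale if any |coord| >= 10^4
  scale <- 1
  maxc <- max(abs(xyz))
  if (maxc >= 9999) {
    scale <- 999 / maxc
    xyz <- xyz * scale
  }
  tad <- if ("tad" %in% names(conf)) conf$tad else rep(1L, nrow(xyz))
  chains <- LETTERS[((as.integer(factor(tad)) - 1L) %% 26L) + 1L]
  lines <- c(
    "REMARK   3D chromosome model; pseudo-atoms, coordinates in micrometres",
    sprintf("REMARK   coordinate scale factor applied: %.6g", scale)
  )
  for (i in seq_len(nrow(xyz))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  BEA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      i %% 100000, chains[i], i %% 10000, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
  }
  for (i in seq_len(nrow(xyz) - 1)) {
    lines <- c(lines, sprintf("CONECT%5d%5d", i, i + 1))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Shared numeric table reader tolerating comma or whitespace separation.
read_numeric_table <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) {
    df <- utils::read.csv(path, header = FALSE)
  } else {
    df <- utils::read.table(path, header = FALSE)
  }
  ok_col <- function(x) is.numeric(x) || all(is.na(x))
  if (!all(vapply(df, ok_col, logical(1)))) {
    # retry assuming a header row
    df <- if (grepl(",", first)) utils::read.csv(path, header = TRUE)
          else utils::read.table(path, header = TRUE)
  }
  if (!all(vapply(df, ok_col, logical(1)))) {
    abort(paste0("non-numeric entries in ", path))
  }
  df[] <- lapply(df, as.numeric)
  df
}
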