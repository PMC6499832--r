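# Model-quality metrics: relative error against FISH distances, A/B
# compartment calling from the model geometry, asphericity, TAD packing
# density, Hi-C/FISH consistency, and Procrustes alignment.

#' Relative-error matrix against FISH distances
#'
#' `RE_ij = |d_ij - F_ij| / F_ij` per TAD pair, where `d_ij` is either
#' the distance between TAD centre points (`mode = "tad_level"`, for
#' backbone models with one point per TAD) or the mean pairwise distance
#' between all loci of TAD i and all loci of TAD j (`mode = "final"`,
#' for full-resolution models carrying a `tad` column).  Pairs with a
#' missing FISH entry are skipped.
#'
#' @param conf Conformation tibble.
#' @param fish `fish_dist` matrix (µm).
#' @param mode `"tad_level"` or `"final"`.
#' @return List with `re` (symmetric matrix, `NA` where FISH is missing)
#'   and `mean_re` (mean over defined off-diagonal pairs).
#' @export
relative_error <- function(conf, fish, mode = c("tad_level", "final")) {
  mode <- match.arg(mode)
  Fm <- unclass(as.matrix(fish))
  m <- nrow(Fm)
  if (mode == "tad_level") {
    xyz <- coords_matrix(conf)
    if (nrow(xyz) != m) abort("one point per TAD expected")
    D <- pairwise_distances(xyz)
  } else {
    stopifnot("tad" %in% names(conf))
    D <- cross_tad_mean_distance(conf, m)
  }
  re <- abs(D - Fm) / Fm
  diag(re) <- 0
  re[is.na(Fm)] <- NA
  off <- row(re) != col(re)
  list(re = re, mean_re = mean(re[off], na.rm = TRUE))
}

# Mean pairwise locus distance between every pair of TADs.
cross_tad_mean_distance <- function(conf, m) {
  xyz <- coords_matrix(conf)
  tad <- conf$tad
  stopifnot(length(unique(tad)) == m)
  D <- pairwise_distances(xyz)
  out <- matrix(0, m, m)
  idx <- split(seq_len(nrow(xyz)), tad)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j) {
        out[i, j] <- out[j, i] <- mean(D[idx[[i]], idx[[j]]])
      }
    }
  }
  out
}

#' Call A/B-like compartments from model geometry
#'
#' Transplants the classical Hi-C compartment call to distance space:
#' the pairwise TAD-centre distance matrix is turned into a column-wise
#' Pearson correlation matrix, and the sign of the leading principal
#' component of that correlation matrix labels each TAD +1 or -1.  The
#' labels carry no intrinsic A/B identity (that requires epigenetic
#' tracks); compare them with [compartment_accuracy()], which maximises
#' over the two label permutations.
#'
#' @param conf Conformation with one point per TAD (backbone), or a
#'   full-resolution model with a `tad` column (TAD centroids are used).
#' @return Integer vector of ±1 labels (zero scores map to +1); the sign
#'   convention is fixed so the largest-magnitude score is positive.
#' @export
call_compartments <- function(conf) {
  xyz <- tad_centres(conf)
  if (nrow(xyz) < 4) abort("compartment calling needs at least 4 TADs")
  D <- pairwise_distances(xyz)
  C <- suppressWarnings(cor(D))
  if (any(!is.finite(C))) {
    warn("degenerate distance profiles: compartment call is arbitrary")
    C[!is.finite(C)] <- 0
  }
  pc <- prcomp(C, center = TRUE, scale. = FALSE)
  sdev <- pc$sdev
  if (sdev[1] < 1e-12 ||
      (length(sdev) > 1 && (sdev[1] - sdev[2]) / sdev[1] < 1e-8)) {
    warn(paste("degenerate distance profiles: leading component is not",
               "unique, compartment labels are arbitrary"))
  }
  scores <- pc$x[, 1]
  if (scores[which.max(abs(scores))] < 0) scores <- -scores
  labels <- ifelse(scores >= 0, 1L, -1L)
  labels
}

tad_centres <- function(conf) {
  if ("tad" %in% names(conf) && anyDuplicated(conf$tad) > 0) {
    conf |>
      group_by(.data$tad) |>
      summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                .groups = "drop") |>
      arrange(.data$tad) |>
      coords_matrix()
  } else {
    coords_matrix(conf)
  }
}

#' Agreement between two ±1 labelings, up to global label swap
#'
#' @param labels,reference Vectors of ±1 labels.
#' @return Fraction of agreeing TADs, maximised over the two label
#'   permutations.
#' @export
compartment_accuracy <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  max(mean(labels == reference), mean(labels == -reference))
}

#' Asphericity of a model
#'
#' Gyration-tensor shape measure: with eigenvalues
#' `l1 >= l2 >= l3` of the gyration tensor,
#' `b = (l1 - (l2 + l3)/2) / (l1 + l2 + l3)`: 0 for an isotropic
#' (spherical) mass distribution, 1 for a rod.
#'
#' @param conf Conformation tibble or n x 3 matrix.
#' @return Scalar in `[0, 1]`.
#' @export
asphericity <- function(conf) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  centred <- sweep(xyz, 2, colMeans(xyz))
  gyr <- crossprod(centred) / nrow(xyz)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  total <- sum(ev)
  if (total <= 0) return(0)
  (ev[1] - (ev[2] + ev[3]) / 2) / total
}

#' Packing density of a TAD fragment
#'
#' Genomic content per unit hull volume: TAD length (bp) divided by the
#' convex-hull volume of the fragment's points (µm³).
#'
#' @param conf Conformation of the fragment (tibble or matrix).
#' @param length_bp Genomic length of the TAD in bp.
#' @return Density in bp/µm³.
#' @export
tad_density <- function(conf, length_bp) {
  stopifnot(length_bp > 0)
  v <- convex_hull_volume(conf)
  if (v <= 0) abort("degenerate fragment: hull volume is 0")
  length_bp / v
}

#' Consistency between Hi-C contacts and FISH distances
#'
#' Over all pairs of TAD pairs `{(i,j), (k,l)}` with defined entries,
#' the fraction where the ordering by contact frequency is opposite to
#' the ordering by FISH distance (higher contact with shorter distance);
#' ties in either quantity are excluded.
#'
#' @param contacts `contact_map` over TADs.
#' @param fish `fish_dist` matrix of the same dimension.
#' @return Fraction in `[0, 1]`; 1 means perfectly consistent.
#' @export
hic_fish_consistency <- function(contacts, fish) {
  f <- unclass(as.matrix(contacts))
  Fm <- unclass(as.matrix(fish))
  stopifnot(all(dim(f) == dim(Fm)))
  ut <- upper.tri(f)
  ok <- ut & !is.na(Fm)
  fv <- f[ok]
  dv <- Fm[ok]
  df <- outer(fv, fv, `-`)
  dd <- outer(dv, dv, `-`)
  keep <- upper.tri(df) & df != 0 & dd != 0
  if (!any(keep)) abort("no comparable pairs of pairs (all tied)")
  mean(sign(df[keep]) != sign(dd[keep]))
}

#' Procrustes superposition of a model onto a reference
#'
#' Optimal similarity transform (rotation, translation, isotropic scale;
#' reflections permitted) minimising the RMSD between matched points.
#' The rotation is obtained from the singular value decomposition of the
#' cross-covariance (via [vegan::procrustes()]).
#'
#' @param model,reference Conformation tibbles or n x 3 matrices with
#'   matched rows.
#' @param scale Allow isotropic scaling (default `TRUE`).
#' @return List with `aligned` (transformed model coordinates, n x 3)
#'   and `rmsd`.
#' @export
align_procrustes <- function(model, reference, scale = TRUE) {
  X <- if (is.data.frame(reference)) coords_matrix(reference) else reference
  Y <- if (is.data.frame(model)) coords_matrix(model) else model
  stopifnot(nrow(X) == nrow(Y))
  pr <- vegan::procrustes(X, Y, scale = scale, symmetric = FALSE)
  # vegan returns the rotated configuration centred at the origin;
  # restore the reference centroid so coordinates are comparable
  aligned <- sweep(pr$Yrot, 2, colMeans(X), `+`)
  list(aligned = aligned,
       rmsd = sqrt(mean(rowSums((aligned - X)^2))),
       rotation = pr$rotation, scale = pr$scale)
}

#' Full evaluation report for a reconstructed model
#'
#' @param conf Model conformation: backbone (one point per TAD) or final
#'   model (with `tad` column).
#' @param fish `fish_dist` matrix.
#' @param tads Optional TAD set tibble (enables per-TAD densities for
#'   final models).
#' @param contacts Optional TAD-level `contact_map` (enables the Hi-C/
#'   FISH consistency statistic).
#' @param reference_labels Optional planted/known ±1 compartment labels.
#' @return A `chromfold_report` with the relative-error matrix and a
#'   one-row `summary` tibble; `glance()` returns the summary.
#' @export
evaluate_model <- function(conf, fish, tads = NULL, contacts = NULL,
                           reference_labels = NULL) {
  final <- "tad" %in% names(conf) && anyDuplicated(conf$tad) > 0
  re <- relative_error(conf, fish, mode = if (final) "final" else
                       "tad_level")
  labels <- call_compartments(conf)
  acc <- if (!is.null(reference_labels)) {
    compartment_accuracy(labels, reference_labels)
  } else NA_real_
  densities <- NULL
  if (final && !is.null(tads)) {
    densities <- vapply(seq_len(nrow(tads)), function(i) {
      tad_density(dplyr::filter(conf, .data$tad == i),
                  tads$end[i] - tads$start[i])
    }, numeric(1))
  }
  consistency <- if (!is.null(contacts)) {
    hic_fish_consistency(contacts, fish)
  } else NA_real_
  summary <- tibble(
    mean_re = re$mean_re,
    compartment_accuracy = acc,
    asphericity = asphericity(conf),
    mean_tad_density = if (is.null(densities)) NA_real_
                       else mean(densities),
    hic_fish_consistency = consistency,
    n_tads = length(labels),
    n_points = nrow(conf))
  structure(list(re = re$re, labels = labels, densities = densities,
                 summary = summary),
            class = "chromfold_report")
}

#' @export
print.chromfold_report <- function(x, ...) {
  cat("<chromfold_report>\n")
  print(x$summary)
  invisible(x)
}
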