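# Polymer conformational energy: the biophysical prior that keeps
# consecutive loci chained at a preferred bond length and penalises
# non-adjacent loci that approach closer than an excluded-volume radius.
#
#   E = sum_consecutive  k_s (||dy|| - b)^2
#     + sum_{|i-j|>1}    k_r max(0, r_c - ||dy||)^2
#
# This is the minimal harmonic-chain + soft-sphere prior; it is kept
# behind one interface so richer forms (bending, torsion) can be swapped
# without touching the fitting code.

#' Polymer energy parameters
#'
#' @param rest_length Preferred distance `b` between consecutive points
#'   (µm).
#' @param stretch_stiffness Harmonic bond constant `k_s` (energy/µm²).
#' @param contact_radius Excluded-volume radius `r_c` (µm); non-adjacent
#'   points closer than this are penalised.
#' @param repulsion_stiffness Soft-sphere constant `k_r` (energy/µm²).
#' @return A `polymer_params` list.
#' @export
polymer_params <- function(rest_length = 0.4, stretch_stiffness = 1,
                           contact_radius = rest_length / 2,
                           repulsion_stiffness = 1) {
  stopifnot(rest_length > 0, stretch_stiffness > 0, contact_radius > 0,
            repulsion_stiffness > 0)
  structure(list(rest_length = rest_length,
                 stretch_stiffness = stretch_stiffness,
                 contact_radius = contact_radius,
                 repulsion_stiffness = repulsion_stiffness),
            class = "polymer_params")
}

#' Scale-aware default polymer parameters
#'
#' Sets the rest length to the median of the distances the data itself
#' implies: for a backbone problem, the median FISH distance between
#' genomically adjacent TADs; for an intra-TAD problem, the spatial step
#' `c * (bin size)^beta` implied by the FISH genomic-to-spatial power law.
#'
#' @param fish Optional `fish_dist` matrix (backbone case).
#' @param powerlaw Optional list/vector with elements `c` and `beta`
#'   (intra-TAD case).
#' @param bin_size Bin width in bp (intra-TAD case).
#' @return A `polymer_params` list.
#' @export
default_polymer_params <- function(fish = NULL, powerlaw = NULL,
                                   bin_size = 5000) {
  b <- if (!is.null(fish)) {
    n <- nrow(fish)
    stats::median(fish[cbind(seq_len(n - 1), seq_len(n - 1) + 1)],
                  na.rm = TRUE)
  } else if (!is.null(powerlaw)) {
    powerlaw[["c"]] * bin_size^powerlaw[["beta"]]
  } else {
    0.4
  }
  if (!is.finite(b) || b <= 0) b <- 0.4
  polymer_params(rest_length = b)
}

#' Polymer conformational energy and analytic gradient
#'
#' @param xyz n x 3 coordinate matrix (µm), or a conformation tibble.
#' @param params A [polymer_params()] list.
#' @return List with `energy` (non-negative scalar) and `gradient`
#'   (n x 3 matrix).  Coincident non-adjacent points contribute zero
#'   gradient direction by convention.
#' @export
polymer_energy <- function(xyz, params = polymer_params()) {
  if (is.data.frame(xyz)) xyz <- coords_matrix(xyz)
  n <- nrow(xyz)
  if (n < 2) abort("polymer energy needs at least 2 points")
  b <- params$rest_length
  ks <- params$stretch_stiffness
  rc <- params$contact_radius
  kr <- params$repulsion_stiffness

  grad <- matrix(0, n, 3)

  # harmonic stretching of consecutive bonds
  dvec <- xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE]
  dlen <- sqrt(rowSums(dvec^2))
  e_stretch <- ks * sum((dlen - b)^2)
  nz <- dlen > 0
  coef <- numeric(n - 1)
  coef[nz] <- 2 * ks * (dlen[nz] - b) / dlen[nz]
  gb <- dvec * coef                       # d e_bond / d (second endpoint)
  grad[-1, ] <- grad[-1, , drop = FALSE] + gb
  grad[-n, ] <- grad[-n, , drop = FALSE] - gb

  # soft-sphere repulsion between non-adjacent pairs
  e_rep <- 0
  if (n > 2) {
    D <- pairwise_distances(xyz)
    sep <- abs(row(D) - col(D))
    pen <- (D < rc) & (sep > 1)
    if (any(pen)) {
      over <- matrix(0, n, n)
      over[pen] <- rc - D[pen]
      e_rep <- kr * sum(over[upper.tri(over)]^2)
      cmat <- matrix(0, n, n)
      ok <- pen & D > 0
      cmat[ok] <- -2 * kr * (rc - D[ok]) / D[ok]
      grad <- grad + (rowSums(cmat) * xyz - cmat %*% xyz)
    }
  }
  list(energy = e_stretch + e_rep, gradient = grad)
}
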