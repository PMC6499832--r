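# TAD-level backbone embedding.
#
# The backbone objective is
#
#   C_g = C1 + lambda_E * C2 + lambda_F * C3
#
# where C1 is the Kullback-Leibler divergence between the Hi-C neighbour
# affinities p_ij and the embedding probabilities q_ij of the current
# model, C2 is the polymer conformational energy, and C3 is the squared
# mismatch to the FISH mean-distance restraints.  All pairwise sums run
# over ordered pairs (i, j), i != j, so every unordered pair is counted
# twice; gradients are the exact analytic gradients of the costs as
# summed this way.

#' Neighbour affinities from a contact map
#'
#' Normalises interaction frequencies over ordered off-diagonal pairs:
#' `p_ij = f_ij / sum_{i != j} f_ij`, so `sum p = 1` and `p_ii = 0`.
#'
#' @param contacts A `contact_map` (or plain symmetric matrix).
#' @return Affinity matrix `P` of the same dimension.
#' @export
hic_affinity <- function(contacts) {
  f <- unclass(as.matrix(contacts))
  diag(f) <- 0
  total <- sum(f)
  if (total <= 0) abort("contact map has no off-diagonal signal")
  f / total
}

#' Embedding probabilities of a conformation
#'
#' Student-like kernel on Euclidean distance:
#' `q_ij = (1 + d_ij)^-1 / sum_{k != l} (1 + d_kl)^-1` over ordered pairs.
#'
#' @param conf Conformation tibble or n x 3 coordinate matrix.
#' @return Probability matrix `Q` with zero diagonal, `sum Q = 1`.
#' @export
embedding_prob <- function(conf) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  if (nrow(xyz) < 2) abort("need at least 2 points")
  w <- 1 / (1 + pairwise_distances(xyz))
  diag(w) <- 0
  w / sum(w)
}

#' Kullback-Leibler cost between affinity and embedding distributions
#'
#' `C1 = sum_{i != j} p_ij log(p_ij / q_ij)` with the convention
#' `0 log 0 = 0`.  Non-negative, zero iff `P == Q`.
#'
#' @param P,Q Same-dimension probability matrices (zero diagonals).
#' @return Scalar `C1`.
#' @export
kl_cost <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  off <- row(P) != col(P)
  p <- P[off]
  q <- Q[off]
  pos <- p > 0
  if (any(q[pos] <= 0)) abort("Q must be strictly positive where P > 0")
  sum(p[pos] * log(p[pos] / q[pos]))
}

# C1 and its gradient with respect to the coordinates.
# dC1/dx_i = sum_j 2 (p_ij - q_ij) / ((1 + d_ij) d_ij) (x_i - x_j).
kl_cost_grad <- function(xyz, P) {
  D <- pairwise_distances(xyz)
  w <- 1 / (1 + D)
  diag(w) <- 0
  Q <- w / sum(w)
  cost <- kl_cost(P, Q)
  cmat <- matrix(0, nrow(D), ncol(D))
  ok <- D > 0 & row(D) != col(D)
  cmat[ok] <- 2 * (P[ok] - Q[ok]) / ((1 + D[ok]) * D[ok])
  grad <- rowSums(cmat) * xyz - cmat %*% xyz
  list(cost = cost, gradient = grad)
}

#' FISH restraint cost and gradient
#'
#' `C3 = sum_{i != j} (d_ij - F_ij)^2` over ordered pairs with a defined
#' FISH measurement; missing (`NA`) entries are skipped.
#'
#' @param conf Conformation tibble or n x 3 matrix (µm).
#' @param fish A `fish_dist` matrix of matching dimension.
#' @return List with `cost` and `gradient` (n x 3).
#' @export
fish_cost <- function(conf, fish) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  stopifnot(nrow(xyz) == nrow(fish))
  D <- pairwise_distances(xyz)
  Fm <- unclass(as.matrix(fish))
  off <- row(D) != col(D) & !is.na(Fm)
  resid <- matrix(0, nrow(D), ncol(D))
  resid[off] <- D[off] - Fm[off]
  cost <- sum(resid[off]^2)
  # each unordered pair appears twice in the cost, hence the factor 4
  cmat <- matrix(0, nrow(D), ncol(D))
  ok <- off & D > 0
  cmat[ok] <- 4 * resid[ok] / D[ok]
  grad <- rowSums(cmat) * xyz - cmat %*% xyz
  list(cost = cost, gradient = grad)
}

#' Backbone cost function `C_g` and gradient
#'
#' @param conf Conformation tibble or n x 3 matrix.
#' @param affinity Affinity matrix from [hic_affinity()].
#' @param fish Optional `fish_dist` matrix (required when
#'   `lambda_F > 0`).
#' @param lambda_E,lambda_F Term weights (>= 0).
#' @param polymer [polymer_params()] for the energy term.
#' @return List with `cost`, `gradient`, and the individual `terms`
#'   (`C1`, `C2`, `C3`).
#' @export
backbone_cost <- function(conf, affinity, fish = NULL, lambda_E = 0,
                          lambda_F = 0, polymer = polymer_params()) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  kl <- kl_cost_grad(xyz, affinity)
  cost <- kl$cost
  grad <- kl$gradient
  terms <- c(C1 = kl$cost, C2 = 0, C3 = 0)
  if (lambda_E > 0) {
    en <- polymer_energy(xyz, polymer)
    terms["C2"] <- en$energy
    cost <- cost + lambda_E * en$energy
    grad <- grad + lambda_E * en$gradient
  }
  if (lambda_F > 0) {
    if (is.null(fish)) abort("lambda_F > 0 requires a FISH matrix (C3)")
    fc <- fish_cost(xyz, fish)
    terms["C3"] <- fc$cost
    cost <- cost + lambda_F * fc$cost
    grad <- grad + lambda_F * fc$gradient
  }
  list(cost = cost, gradient = grad, terms = terms)
}

#' Fit the TAD-level backbone model
#'
#' Embeds one 3D point per TAD by gradient descent on
#' `C_g = C1 + lambda_E C2 + lambda_F C3` from a seeded Gaussian
#' initialisation, with backtracking step halving so the cost trajectory
#' is monotone non-increasing.
#'
#' @param contacts TAD-level `contact_map`.
#' @param fish Optional `fish_dist` matrix (same dimension).
#' @param lambda_E,lambda_F Term weights.
#' @param polymer [polymer_params()]; defaults to scale-aware parameters
#'   derived from `fish` when available.
#' @param opt [optimizer_config()].
#' @param tads Optional TAD set tibble attached to the result as locus
#'   metadata.
#' @return A `chromfold_fit` object; `$conformation` holds the embedded
#'   backbone, `tidy()` returns per-point coordinates, `glance()` a
#'   one-row fit summary.
#' @export
fit_backbone <- function(contacts, fish = NULL,
                         lambda_E = lambda_defaults()$backbone["lambda_E"],
                         lambda_F = lambda_defaults()$backbone["lambda_F"],
                         polymer = NULL, opt = optimizer_config(),
                         tads = NULL) {
  P <- hic_affinity(contacts)
  n <- nrow(P)
  if (!is.null(fish) && nrow(fish) != n) {
    abort("FISH matrix dimension must match the contact map")
  }
  if (is.null(polymer)) polymer <- default_polymer_params(fish = fish)
  scale <- opt$init_scale
  if (is.null(scale)) {
    scale <- if (!is.null(fish)) {
      mean(fish[row(fish) != col(fish)], na.rm = TRUE) / 2
    } else 1
  }
  fn <- function(x) {
    backbone_cost(x, P, fish, lambda_E, lambda_F, polymer)
  }
  x0 <- init_coords(n, scale, opt$seed)
  res <- gd_minimize(x0, fn, opt)
  final <- fn(res$x)
  bins <- if (!is.null(tads)) tads else tibble(tad = seq_len(n))
  new_chromfold_fit(
    conformation = conformation(res$x, bins),
    trajectory = res$trajectory,
    terms = final$terms,
    lambda = c(lambda_E = unname(lambda_E), lambda_F = unname(lambda_F)),
    iterations = res$iterations,
    converged = res$converged,
    kind = "backbone")
}

#' Default term weights
#'
#' The published defaults for raw-count Hi-C input: backbone
#' `lambda_E = 5e12`, `lambda_F = 1e-8`; intra-TAD `lambda_E = 5e11`,
#' `lambda_R = 1e-7`.  These weights balance terms whose magnitudes
#' depend on the scale of the input contact counts, so they should be
#' re-selected with [tune_lambda()] for inputs on other scales.
#'
#' @return A list with elements `backbone` and `tad`.
#' @export
lambda_defaults <- function() {
  list(backbone = c(lambda_E = 5e12, lambda_F = 1e-8),
       tad = c(lambda_E = 5e11, lambda_R = 1e-7))
}

new_chromfold_fit <- function(conformation, trajectory, terms, lambda,
                              iterations, converged, kind) {
  structure(list(conformation = conformation, trajectory = trajectory,
                 terms = terms, lambda = lambda, iterations = iterations,
                 converged = converged, kind = kind),
            class = "chromfold_fit")
}

#' @export
print.chromfold_fit <- function(x, ...) {
  cat(sprintf("<chromfold_fit: %s>\n", x$kind))
  cat(sprintf("  points: %d   iterations: %d   converged: %s\n",
              nrow(x$conformation), x$iterations, x$converged))
  cat(sprintf("  final cost: %.6g  (%s)\n",
              tail(x$trajectory, 1),
              paste(sprintf("%s=%.4g", names(x$terms), x$terms),
                    collapse = ", ")))
  invisible(x)
}
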