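# Parameter selection: grid search on the volume-matching score
#
#   S = (1 - C1) * v / |v - v'|
#
# where C1 is the (clamped) KL mismatch of the fitted model, v a prior
# volume estimate for the chromosome or TAD, and v' the convex-hull
# volume of the reconstructed model.  The ratio diverges as v' -> v, so
# it is regularised with a floor of eps * v on the denominator; larger S
# is better.

#' Convex-hull volume of a model
#'
#' @param conf Conformation tibble or n x 3 matrix.
#' @return Volume in µm³ (0 with a warning for degenerate point sets).
#' @export
model_volume <- function(conf) {
  convex_hull_volume(conf)
}

#' Volume-matching parameter-selection score
#'
#' `S = (1 - min(C1, 1)) * v / max(|v - v'|, eps * v)`.  `C1` is clamped
#' to `[0, 1]` (the globally normalised KL divergence can exceed 1) and
#' the denominator is floored so the score is finite at `v' = v`; its
#' capped maximum at `C1 = 0`, `v' = v` is `1/eps`.
#'
#' @param C1 KL mismatch of the fitted model.
#' @param v Prior volume estimate (µm³, > 0).
#' @param v_prime Volume of the reconstructed model (µm³).
#' @param eps Regularisation floor (fraction of `v`).
#' @return Scalar score; larger is better.
#' @export
score_lambda <- function(C1, v, v_prime, eps = 1e-3) {
  stopifnot(v > 0, eps > 0)
  c1 <- pmin(pmax(C1, 0), 1)
  (1 - c1) * v / pmax(abs(v - v_prime), eps * v)
}

#' Prior chromosome/TAD volume from the FISH power law
#'
#' Converts the FISH genomic-to-spatial scaling into a rough volume
#' prior: the radius of gyration implied by `c * L^beta / sqrt(6)` is
#' inflated to an effective spherical radius `1.29 * R_g` (the radius of
#' a uniform ball with that radius of gyration is `sqrt(5/3) R_g`,
#' approximately `1.29 R_g`), giving `v = (4/3) pi (1.29 R_g)^3`.
#' Direct experimental estimates should be preferred when available.
#'
#' @param length_bp Genomic length (bp).
#' @param powerlaw List with `c` and `beta` from
#'   [fit_distance_powerlaw()].
#' @return Volume in µm³.
#' @export
estimate_volume_prior <- function(length_bp, powerlaw) {
  rg <- estimate_target_rg(length_bp, powerlaw)
  (4 / 3) * pi * (1.29 * rg)^3
}

#' Grid search over term weights
#'
#' Runs a fitter at every point of a two-dimensional weight grid and
#' scores each fitted model with [score_lambda()]; returns the score
#' table and the best pair.  Ties break toward the smaller first weight,
#' then the smaller second weight.
#'
#' @param fitter Function `(lambda1, lambda2) -> chromfold_fit`.
#' @param grid1,grid2 Numeric vectors of candidate weights (first weight
#'   is `lambda_E`; second is `lambda_F` for backbones, `lambda_R` for
#'   TADs).
#' @param v Prior volume (µm³).
#' @param names Character vector of length 2 naming the two weights.
#' @return A `chromfold_tune`: `$table` tibble with one row per grid
#'   point (weights, `C1`, `v`, `v_prime`, `S`), `$best` the winning row.
#' @export
tune_lambda <- function(fitter, grid1, grid2, v,
                        names = c("lambda_E", "lambda_F")) {
  if (length(grid1) == 0 || length(grid2) == 0) abort("empty grid")
  rows <- list()
  for (l1 in sort(grid1)) {
    for (l2 in sort(grid2)) {
      fit <- fitter(l1, l2)
      vol <- model_volume(fit$conformation)
      c1 <- unname(fit$terms["C1"])
      rows[[length(rows) + 1]] <- tibble(
        l1 = l1, l2 = l2, C1 = c1, v = v, v_prime = vol,
        S = score_lambda(c1, v, vol))
    }
  }
  table <- bind_rows(rows)
  names(table)[1:2] <- names
  # argmax S; grids are iterated sorted ascending so the first maximal
  # row realises the documented tie-break
  best <- table[which.max(table$S), ]
  structure(list(table = table, best = best, names = names),
            class = "chromfold_tune")
}

#' Grid search for the backbone weights
#'
#' @param contacts TAD-level `contact_map`.
#' @param fish `fish_dist` matrix.
#' @param lambda_E_grid,lambda_F_grid Candidate weights; default grids
#'   are log-spaced around the published defaults.
#' @param v Prior chromosome volume (µm³); see
#'   [estimate_volume_prior()].
#' @param opt [optimizer_config()].
#' @param ... Passed to [fit_backbone()].
#' @return A `chromfold_tune`.
#' @export
tune_backbone <- function(contacts, fish, v,
                          lambda_E_grid = 5e12 * 10^(-2:2),
                          lambda_F_grid = 1e-8 * 10^(-2:2),
                          opt = optimizer_config(), ...) {
  tune_lambda(function(l1, l2) {
    fit_backbone(contacts, fish, lambda_E = l1, lambda_F = l2, opt = opt,
                 ...)
  }, lambda_E_grid, lambda_F_grid, v,
  names = c("lambda_E", "lambda_F"))
}

#' Grid search for the intra-TAD weights
#'
#' @param contacts Intra-TAD `contact_map`.
#' @param target_rg Target radius of gyration (µm).
#' @param v Prior TAD volume (µm³).
#' @param lambda_E_grid,lambda_R_grid Candidate weights.
#' @param opt [optimizer_config()].
#' @param ... Passed to [fit_tad()].
#' @return A `chromfold_tune`.
#' @export
tune_tad <- function(contacts, target_rg, v,
                     lambda_E_grid = 5e11 * 10^(-2:2),
                     lambda_R_grid = 1e-7 * 10^(-2:2),
                     opt = optimizer_config(), ...) {
  tune_lambda(function(l1, l2) {
    fit_tad(contacts, target_rg = target_rg, lambda_E = l1, lambda_R = l2,
            opt = opt, ...)
  }, lambda_E_grid, lambda_R_grid, v,
  names = c("lambda_E", "lambda_R"))
}

#' @export
print.chromfold_tune <- function(x, ...) {
  cat("<chromfold_tune>\n")
  cat(sprintf("  grid points: %d\n", nrow(x$table)))
  cat(sprintf("  best: %s = %.4g, %s = %.4g (S = %.4g)\n",
              x$names[1], x$best[[1]], x$names[2], x$best[[2]],
              x$best$S))
  invisible(x)
}
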