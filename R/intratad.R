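# Intra-TAD modelling at fixed bin resolution (default 5 kb).
#
# FISH gives no restraints inside a TAD, but it pins down a rough target
# radius of gyration for the TAD through the genomic-to-spatial power law
# fitted across TAD pairs.  The intra-TAD objective is
#
#   C_t = C1 + lambda_E * C2 + lambda_R * C4,
#   C4  = | R_g^2 - Rg_target^2 |.

#' Radius-of-gyration constraint cost and gradient
#'
#' `C4 = |R_g^2 - target^2|` with subgradient
#' `(2/N) sign(R_g^2 - target^2) (y_i - ybar)`; `sign(0) = 0`.
#'
#' @param conf Conformation tibble or n x 3 matrix.
#' @param target_rg Target radius of gyration (µm, > 0).
#' @return List with `cost` and `gradient`.
#' @export
rg_cost <- function(conf, target_rg) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  stopifnot(target_rg > 0)
  n <- nrow(xyz)
  centred <- sweep(xyz, 2, colMeans(xyz))
  rg2 <- mean(rowSums(centred^2))
  diffsq <- rg2 - target_rg^2
  list(cost = abs(diffsq),
       gradient = (2 / n) * sign(diffsq) * centred)
}

#' Estimate a TAD's target radius of gyration from the FISH power law
#'
#' Applies the genomic-to-spatial scaling `d = c * L^beta` fitted across
#' TAD pairs (see [fit_distance_powerlaw()]) to the TAD's own genomic
#' length to estimate its spatial extent, then converts the end-to-end
#' estimate to a radius of gyration through the ideal-chain relation
#' `R_g = R_end / sqrt(6)`.  Direct per-TAD measurements, when available,
#' should be passed to [fit_tad()] instead.
#'
#' @param length_bp Genomic length of the TAD (bp, > 0).
#' @param powerlaw List/vector with `c` (µm per bp^beta) and `beta`.
#' @return Target radius of gyration (µm).
#' @export
estimate_target_rg <- function(length_bp, powerlaw) {
  if (any(length_bp <= 0)) abort("TAD length must be positive")
  powerlaw[["c"]] * length_bp^powerlaw[["beta"]] / sqrt(6)
}

#' Intra-TAD cost function `C_t` and gradient
#'
#' @inheritParams backbone_cost
#' @param target_rg Target radius of gyration (µm); required when
#'   `lambda_R > 0`.
#' @param lambda_R Weight of the radius-of-gyration constraint.
#' @return List with `cost`, `gradient`, `terms` (`C1`, `C2`, `C4`).
#' @export
tad_cost <- function(conf, affinity, target_rg = NULL, lambda_E = 0,
                     lambda_R = 0, polymer = polymer_params()) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  kl <- kl_cost_grad(xyz, affinity)
  cost <- kl$cost
  grad <- kl$gradient
  terms <- c(C1 = kl$cost, C2 = 0, C4 = 0)
  if (lambda_E > 0) {
    en <- polymer_energy(xyz, polymer)
    terms["C2"] <- en$energy
    cost <- cost + lambda_E * en$energy
    grad <- grad + lambda_E * en$gradient
  }
  if (lambda_R > 0) {
    if (is.null(target_rg)) abort("lambda_R > 0 requires target_rg (C4)")
    rg <- rg_cost(xyz, target_rg)
    terms["C4"] <- rg$cost
    cost <- cost + lambda_R * rg$cost
    grad <- grad + lambda_R * rg$gradient
  }
  list(cost = cost, gradient = grad, terms = terms)
}

#' Fit the 3D model of a single TAD
#'
#' Embeds one point per intra-TAD bin by gradient descent on
#' `C_t = C1 + lambda_E C2 + lambda_R C4`.
#'
#' @param contacts Intra-TAD `contact_map` at bin resolution.
#' @param target_rg Target radius of gyration (µm): a direct estimate, or
#'   the value from [estimate_target_rg()].
#' @param lambda_E,lambda_R Term weights.
#' @param polymer [polymer_params()]; defaults to a rest length matched
#'   to the target radius of gyration.
#' @param opt [optimizer_config()].
#' @param bins Optional per-bin metadata tibble.
#' @return A `chromfold_fit` object (kind `"tad"`).
#' @export
fit_tad <- function(contacts, target_rg = NULL,
                    lambda_E = lambda_defaults()$tad["lambda_E"],
                    lambda_R = lambda_defaults()$tad["lambda_R"],
                    polymer = NULL, opt = optimizer_config(),
                    bins = NULL) {
  P <- hic_affinity(contacts)
  n <- nrow(P)
  if (is.null(polymer)) {
    # rest length so that an ideal chain of n steps has the target Rg
    b <- if (!is.null(target_rg)) target_rg * sqrt(6 / max(n - 1, 1))
         else 0.05
    polymer <- polymer_params(rest_length = max(b, 1e-3))
  }
  scale <- opt$init_scale
  if (is.null(scale)) {
    scale <- if (!is.null(target_rg)) target_rg else 0.1
  }
  fn <- function(x) tad_cost(x, P, target_rg, lambda_E, lambda_R, polymer)
  x0 <- init_coords(n, scale, opt$seed)
  res <- gd_minimize(x0, fn, opt)
  final <- fn(res$x)
  new_chromfold_fit(
    conformation = conformation(res$x, bins),
    trajectory = res$trajectory,
    terms = final$terms,
    lambda = c(lambda_E = unname(lambda_E), lambda_R = unname(lambda_R)),
    iterations = res$iterations,
    converged = res$converged,
    kind = "tad")
}

#' Fit all TADs of a chromosome
#'
#' Runs [fit_tad()] independently for every TAD; per-TAD seeds are
#' `opt$seed + tad ordinal`, so parallel or sequential execution give the
#' same result.
#'
#' @param intra_contacts List of intra-TAD `contact_map`s, in TAD order.
#' @param target_rgs Numeric vector of per-TAD target radii of gyration
#'   (µm), or `NULL` to skip the constraint.
#' @param ... Passed to [fit_tad()].
#' @param opt [optimizer_config()].
#' @return List of `chromfold_fit` objects.
#' @export
fit_all_tads <- function(intra_contacts, target_rgs = NULL, ...,
                         opt = optimizer_config()) {
  imap(intra_contacts, function(cm, i) {
    o <- opt
    o$seed <- opt$seed + as.integer(i)
    fit_tad(cm, target_rg = if (is.null(target_rgs)) NULL
                            else target_rgs[[as.integer(i)]],
            ..., opt = o)
  })
}
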