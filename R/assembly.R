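# Rigid-body assembly of intra-TAD models into the TAD-level backbone.
#
# Each TAD model is translated so its centroid sits on its backbone
# point, then TAD orientations are optimised by rotating each TAD about
# its centre (with optional mirror reflection) to minimise
#
#   C_integration = sum_{i=1}^{n-1} (||y_{s_{i+1}} - y_{e_i}|| - d_{i,i+1})^2
#
# where y_{e_i}, y_{s_{i+1}} are the last point of TAD i and the first
# point of TAD i+1, and d_{i,i+1} the estimated linker distance between
# the two junction loci.

#' Assembly parameters
#'
#' @param alpha_exponent Contact-to-distance exponent: the linker distance
#'   is `f^alpha` for non-zero junction contact frequency `f`; the
#'   published value is -0.25 (i.e. `f` proportional to `d^-4`).
#' @param c,beta Genomic-to-spatial power law `d = c * g^beta` used when
#'   the junction contact frequency is zero; fit them from FISH data with
#'   [fit_distance_powerlaw()].
#' @param learning_rate Step size for the junction gradient update.
#' @param max_iter Maximum number of sweeps over the TADs.
#' @param rel_tol Relative cost-change convergence threshold per sweep.
#' @param try_reflection Also evaluate each TAD's mirror image and keep
#'   the lower-cost chirality.
#' @param calibrate_scale Rescale the contact-derived linker distances so
#'   their median matches the median of the power-law distances; use when
#'   the contact counts are on an arbitrary scale.
#' @param max_halvings Angle halvings attempted before skipping an update.
#' @return An `assembly_params` list.
#' @export
assembly_params <- function(alpha_exponent = -0.25, c = 1, beta = 1 / 3,
                            learning_rate = 0.1, max_iter = 200,
                            rel_tol = 1e-9, try_reflection = TRUE,
                            calibrate_scale = FALSE, max_halvings = 20) {
  stopifnot(alpha_exponent < 0, c > 0, beta > 0, beta < 1,
            learning_rate > 0, max_iter >= 1)
  structure(list(alpha_exponent = alpha_exponent, c = c, beta = beta,
                 learning_rate = learning_rate, max_iter = max_iter,
                 rel_tol = rel_tol, try_reflection = try_reflection,
                 calibrate_scale = calibrate_scale,
                 max_halvings = max_halvings),
            class = "assembly_params")
}

#' Fit the genomic-to-spatial distance power law from FISH data
#'
#' Ordinary least squares of `log F_ij` on `log g_ij` over TAD pairs with
#' a defined FISH distance, where `g_ij` is the genomic centre-to-centre
#' separation in bp: returns `c = exp(intercept)` and `beta = slope` of
#' `F = c * g^beta`.
#'
#' @param fish A `fish_dist` matrix.
#' @param tads Matching TAD set tibble.
#' @return A list with elements `c` and `beta`.
#' @export
fit_distance_powerlaw <- function(fish, tads) {
  stopifnot(nrow(fish) == nrow(tads))
  g <- tad_genomic_separation(tads)
  ut <- upper.tri(fish)
  ok <- ut & !is.na(unclass(fish)) & g > 0
  if (sum(ok) < 3) abort("need at least 3 usable TAD pairs for the fit")
  fit <- lm(log(unclass(fish)[ok]) ~ log(g[ok]))
  list(c = exp(unname(coef(fit)[1])), beta = unname(coef(fit)[2]))
}

#' Linker distance between adjacent TADs
#'
#' `d = f^alpha` when the junction contact frequency `f` is non-zero,
#' otherwise `d = c * g^beta` from the genomic separation `g` (bp).
#'
#' @param f_link Junction contact frequencies (>= 0), vectorised.
#' @param g_link Genomic distances (bp) between the junction loci; must be
#'   positive wherever `f_link` is zero.
#' @param params [assembly_params()].
#' @return Linker distances in µm.
#' @export
linker_distance <- function(f_link, g_link, params = assembly_params()) {
  if (any(f_link < 0)) abort("junction contact frequencies must be >= 0")
  zero <- f_link == 0
  if (any(zero & (is.na(g_link) | g_link <= 0))) {
    abort("zero junction contact needs a positive genomic distance")
  }
  d <- ifelse(zero, params$c * g_link^params$beta,
              f_link^params$alpha_exponent)
  if (params$calibrate_scale && any(!zero)) {
    target <- stats::median(params$c * g_link[!zero]^params$beta)
    d[!zero] <- d[!zero] * target / stats::median(d[!zero])
  }
  d
}

# Junction contact frequencies and genomic gaps from a full-resolution
# contact map: last bin of TAD i vs first bin of TAD i+1.
junction_inputs <- function(contacts, n_bins_per_tad, tads,
                            resolution = 5000) {
  n_tads <- length(n_bins_per_tad)
  stopifnot(nrow(contacts) == sum(n_bins_per_tad),
            nrow(tads) == n_tads)
  last_bin <- cumsum(n_bins_per_tad)
  first_bin <- c(1, head(last_bin, -1) + 1)
  f_link <- unclass(as.matrix(contacts))[
    cbind(last_bin[-n_tads], first_bin[-1])]
  # genomic separation between the centres of the two junction bins
  g_link <- tads$start[-1] - tads$end[-n_tads] + resolution
  list(f_link = f_link, g_link = g_link)
}

#' Integration cost and junction gradients
#'
#' @param fragments List of n x 3 coordinate matrices (or conformation
#'   tibbles), one per TAD, in genomic order.
#' @param d Numeric vector of n-1 target linker distances (µm).
#' @return List with `cost`, `gaps` (current junction gaps) and
#'   `junction_grad`, an (n-1) x 3 matrix holding the gradient of the
#'   cost with respect to `y_{s_{i+1}}` (the gradient with respect to
#'   `y_{e_i}` is its negative).  Coincident junction points get a zero
#'   gradient.
#' @export
integration_cost <- function(fragments, d) {
  frags <- lapply(fragments, function(f) {
    if (is.data.frame(f)) coords_matrix(f) else f
  })
  n <- length(frags)
  if (length(d) != n - 1) abort("need n - 1 linker distances for n TADs")
  ends <- t(vapply(frags, function(m) m[nrow(m), ], numeric(3)))
  starts <- t(vapply(frags, function(m) m[1, ], numeric(3)))
  delta <- starts[-1, , drop = FALSE] - ends[-n, , drop = FALSE]
  gaps <- sqrt(rowSums(delta^2))
  resid <- gaps - d
  cost <- sum(resid^2)
  grad <- matrix(0, n - 1, 3)
  nz <- gaps > 0
  grad[nz, ] <- 2 * resid[nz] / gaps[nz] * delta[nz, , drop = FALSE]
  list(cost = cost, gaps = gaps, junction_grad = grad)
}

# Rotation that carries endpoint y (lying in a fragment centred at
# `centre`) toward target y', about `centre`; the angle is capped at
# pi/2 per step and can be shrunk by `scale` for backtracking.
rotation_toward <- function(y, centre, target, scale = 1, cap = pi / 2) {
  v <- y - centre
  w <- target - centre
  nv <- sqrt(sum(v^2))
  nw <- sqrt(sum(w^2))
  if (nv < .Machine$double.eps || nw < .Machine$double.eps) {
    return(list(R = diag(3), axis = c(0, 0, 0), angle = 0))
  }
  axis <- pracma_cross(v, w)
  if (sqrt(sum(axis^2)) < 1e-14 * nv * nw) {
    return(list(R = diag(3), axis = c(0, 0, 0), angle = 0))
  }
  cosang <- min(1, max(-1, sum(v * w) / (nv * nw)))
  angle <- min(acos(cosang), cap) * scale
  list(R = rotation_matrix(axis, angle), axis = axis, angle = angle)
}

#' Rotate a TAD fragment so its endpoint moves toward a target point
#'
#' Rigid rotation of the whole fragment about `centre`: the axis is the
#' cross product of `(y - centre)` and `(target - centre)` and the angle
#' is the angle between those vectors, capped at pi/2 per step.  All
#' intra-fragment distances and the fragment centre are preserved.
#'
#' @param fragment Conformation tibble or n x 3 matrix.
#' @param centre Rotation centre (length-3).
#' @param endpoint Row index of the endpoint being steered.
#' @param target Target position `y'` for that endpoint (length-3).
#' @return The rotated fragment (same type as the input).
#' @export
rotate_tad_step <- function(fragment, centre, endpoint, target) {
  xyz <- if (is.data.frame(fragment)) coords_matrix(fragment) else fragment
  rot <- rotation_toward(xyz[endpoint, ], centre, target)
  out <- transform_about(xyz, rot$R, centre)
  if (is.data.frame(fragment)) set_coords(fragment, out) else out
}

#' Assemble intra-TAD models into the backbone
#'
#' Translates every TAD model so its centroid coincides with its backbone
#' point, then runs sweeps in genomic order: each TAD takes a gradient
#' step on its most-strained junction endpoint, converted into a rigid
#' rotation about the TAD centre (angle capped at pi/2, backtracking
#' halving so the integration cost never increases), with an optional
#' mirror-reflection trial per sweep (reflection through the plane
#' perpendicular to the current rotation axis, passing through the
#' centre).
#'
#' @param backbone Backbone conformation (one point per TAD) or a
#'   `chromfold_fit` of kind `"backbone"`.
#' @param tad_models List of per-TAD conformations (tibbles or matrices)
#'   or `chromfold_fit`s, in genomic order.
#' @param d Vector of n-1 linker distances (µm); computed from
#'   `contacts` + `tads` when omitted.
#' @param contacts Optional full-resolution `contact_map` used to derive
#'   linker distances.
#' @param tads Optional TAD set tibble (needed with `contacts`).
#' @param resolution Bin width (bp) of `contacts`.
#' @param params [assembly_params()].
#' @return A `chromfold_assembly`: `$conformation` is the assembled
#'   full-resolution model (with `tad` labels), `$placements` records
#'   per-TAD rotations and reflections, `$trajectory` the cost per sweep.
#' @export
assemble_chromosome <- function(backbone, tad_models, d = NULL,
                                contacts = NULL, tads = NULL,
                                resolution = 5000,
                                params = assembly_params()) {
  if (inherits(backbone, "chromfold_fit")) backbone <- backbone$conformation
  frags <- lapply(tad_models, function(m) {
    if (inherits(m, "chromfold_fit")) m <- m$conformation
    if (is.data.frame(m)) coords_matrix(m) else as.matrix(m)
  })
  metas <- lapply(tad_models, function(m) {
    if (inherits(m, "chromfold_fit")) m <- m$conformation
    if (is.data.frame(m)) m else NULL
  })
  n <- length(frags)
  bb <- coords_matrix(backbone)
  if (nrow(bb) != n) abort("one backbone point per TAD model is required")
  if (is.null(d)) {
    if (is.null(contacts) || is.null(tads)) {
      abort("either d or (contacts, tads) must be supplied")
    }
    ji <- junction_inputs(contacts, vapply(frags, nrow, integer(1)), tads,
                          resolution)
    d <- linker_distance(ji$f_link, ji$g_link, params)
  }
  if (length(d) != n - 1) abort("need n - 1 linker distances for n TADs")

  # (1) translate each TAD so its centroid is the backbone point
  frags <- lapply(seq_len(n), function(i) {
    sweep(frags[[i]], 2, bb[i, ] - centroid(frags[[i]]), `+`)
  })
  rotations <- rep(list(diag(3)), n)
  reflected <- rep(FALSE, n)

  ev <- integration_cost(frags, d)
  trajectory <- ev$cost
  for (sweep_i in seq_len(params$max_iter)) {
    cost_before <- ev$cost
    for (k in seq_len(n)) {
      upd <- orient_tad_once(frags, k, d, bb[k, ], ev, params)
      if (!is.null(upd$frag)) {
        frags[[k]] <- upd$frag
        rotations[[k]] <- upd$R %*% rotations[[k]]
        if (upd$reflected) reflected[k] <- !reflected[k]
        ev <- upd$ev
      }
    }
    trajectory <- c(trajectory, ev$cost)
    rel <- (cost_before - ev$cost) / max(cost_before, 1e-300)
    if (rel < params$rel_tol) break
  }

  conf <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    ci <- conformation(frags[[i]],
                       bins = if (!is.null(metas[[i]])) {
                         metas[[i]][, intersect(c("chrom", "start", "end"),
                                                names(metas[[i]])),
                                    drop = FALSE]
                       } else NULL)
    ci$tad <- i
    ci
  }))
  conf$index <- seq_len(nrow(conf))
  # decompose each accumulated linear map into a proper rotation and a
  # reflection flag (det = -1 means the chirality was flipped)
  reflected <- vapply(rotations, function(L) det(L) < 0, logical(1))
  rotations <- lapply(rotations, function(L) {
    if (det(L) < 0) L %*% reflection_matrix(c(1, 0, 0)) else L
  })
  structure(list(
    conformation = conf,
    placements = tibble(tad = seq_len(n),
                        rotation = rotations,
                        reflected = reflected,
                        centre = lapply(seq_len(n), function(i) bb[i, ])),
    d = d, trajectory = trajectory, cost = ev$cost),
    class = "chromfold_assembly")
}

# One orientation update for TAD k: pick the junction endpoint with the
# larger gradient, convert the gradient step into a rotation (backtracking
# on the angle), then optionally try the mirror image.  Returns NULL frag
# if no improving update exists.
orient_tad_once <- function(frags, k, d, centre, ev, params) {
  n <- length(frags)
  nk <- nrow(frags[[k]])
  # gradient of the cost wrt this TAD's start point (junction k-1) and
  # end point (junction k)
  g_start <- if (k > 1) ev$junction_grad[k - 1, ] else c(0, 0, 0)
  g_end <- if (k < n) -ev$junction_grad[k, ] else c(0, 0, 0)
  use_start <- sqrt(sum(g_start^2)) >= sqrt(sum(g_end^2))
  g <- if (use_start) g_start else g_end
  out <- list(frag = NULL, reflected = FALSE)
  if (sqrt(sum(g^2)) > 0 && nk > 1) {
    row <- if (use_start) 1L else nk
    y <- frags[[k]][row, ]
    target <- y - params$learning_rate * g
    scale <- 1
    for (h in seq_len(params$max_halvings)) {
      rot <- rotation_toward(y, centre, target, scale = scale)
      if (rot$angle == 0) break
      cand <- transform_about(frags[[k]], rot$R, centre)
      trial <- frags
      trial[[k]] <- cand
      ev_new <- integration_cost(trial, d)
      if (ev_new$cost <= ev$cost) {
        out <- list(frag = cand, R = rot$R, reflected = FALSE, ev = ev_new,
                    axis = rot$axis)
        break
      }
      scale <- scale / 2
    }
  }
  if (params$try_reflection) {
    base_frag <- if (!is.null(out$frag)) out$frag else frags[[k]]
    base_ev <- if (!is.null(out$frag)) out$ev else ev
    axis <- if (!is.null(out$frag)) out$axis else g
    M <- reflection_matrix(axis)
    cand <- transform_about(base_frag, M, centre)
    trial <- frags
    trial[[k]] <- cand
    ev_ref <- integration_cost(trial, d)
    if (ev_ref$cost < base_ev$cost) {
      R_prev <- if (!is.null(out$frag)) out$R else diag(3)
      out <- list(frag = cand, R = M %*% R_prev, reflected = TRUE,
                  ev = ev_ref, axis = axis)
    }
  }
  out
}

#' @export
print.chromfold_assembly <- function(x, ...) {
  cat("<chromfold_assembly>\n")
  cat(sprintf("  TADs: %d   points: %d   sweeps: %d\n",
              nrow(x$placements), nrow(x$conformation),
              length(x$trajectory) - 1))
  cat(sprintf("  integration cost: %.6g   reflected TADs: %d\n",
              x$cost, sum(x$placements$reflected)))
  invisible(x)
}
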