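# Shared first-order optimizer: plain gradient descent with backtracking
# step halving, which guarantees a monotone non-increasing cost trajectory.

#' Optimizer configuration
#'
#' @param learning_rate Initial step size per iteration.
#' @param max_iter Maximum number of iterations.
#' @param rel_tol Stop when the relative cost change falls below this.
#' @param seed Seed for the random initialisation.
#' @param init_scale Standard deviation (µm) of the isotropic Gaussian
#'   initialisation; `NULL` derives it from the data (mean FISH distance /
#'   2 when FISH restraints are present).
#' @param max_halvings Maximum backtracking halvings per iteration.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(learning_rate = 0.05, max_iter = 2000,
                             rel_tol = 1e-7, seed = 1, init_scale = NULL,
                             max_halvings = 30) {
  stopifnot(learning_rate > 0, max_iter >= 0, rel_tol >= 0,
            max_halvings >= 1)
  structure(list(learning_rate = learning_rate, max_iter = max_iter,
                 rel_tol = rel_tol, seed = seed, init_scale = init_scale,
                 max_halvings = max_halvings),
            class = "optimizer_config")
}

# Minimise fn_grad(x)$cost by gradient descent with backtracking.
# fn_grad takes an n x 3 matrix and returns list(cost, gradient).
# Returns list(x, trajectory, iterations, converged).
gd_minimize <- function(x, fn_grad, opt) {
  ev <- fn_grad(x)
  if (!is.finite(ev$cost)) abort("initial cost is not finite")
  trajectory <- ev$cost
  converged <- FALSE
  iter <- 0
  while (iter < opt$max_iter) {
    iter <- iter + 1
    g <- ev$gradient
    gnorm <- sqrt(sum(g^2))
    if (gnorm == 0) {
      converged <- TRUE
      break
    }
    step <- opt$learning_rate
    accepted <- FALSE
    for (h in seq_len(opt$max_halvings)) {
      x_new <- x - step * g
      ev_new <- fn_grad(x_new)
      if (is.finite(ev_new$cost) && ev_new$cost <= ev$cost) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE     # no descent step found at the smallest scale
      break
    }
    rel_change <- (ev$cost - ev_new$cost) / max(abs(ev$cost), 1e-300)
    x <- x_new
    ev <- ev_new
    trajectory <- c(trajectory, ev$cost)
    if (rel_change < opt$rel_tol) {
      converged <- TRUE
      break
    }
  }
  list(x = x, trajectory = trajectory, iterations = iter,
       converged = converged, cost = ev$cost)
}

# Seeded isotropic Gaussian initial coordinates.
init_coords <- function(n, scale, seed) {
  withr::with_seed(seed, matrix(rnorm(n * 3, sd = scale), n, 3))
}
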