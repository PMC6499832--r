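# Shared test oracles: central finite differences for gradients, random
# rigid motions, and small fixture builders (all generated in code).

fd_gradient <- function(fn, x, h = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      xp <- x
      xm <- x
      xp[i, j] <- xp[i, j] + h
      xm[i, j] <- xm[i, j] - h
      g[i, j] <- (fn(xp) - fn(xm)) / (2 * h)
    }
  }
  g
}

max_rel_diff <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-12)
}

random_rigid_motion <- function(xyz, seed = 1) {
  withr::with_seed(seed, {
    R <- chromfold::rotation_matrix(rnorm(3), runif(1, 0.1, pi))
    t <- rnorm(3, sd = 2)
    sweep(xyz %*% t(R), 2, t, `+`)
  })
}

random_coords <- function(n, seed, sd = 1) {
  withr::with_seed(seed, matrix(rnorm(n * 3, sd = sd), n, 3))
}

random_contacts <- function(n, seed) {
  withr::with_seed(seed, {
    f <- abs(matrix(rnorm(n * n), n, n)) + 0.1
    chromfold::contact_map(f)
  })
}

random_fish <- function(n, seed, base = 1) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(n * 3), n, 3)
    chromfold::fish_dist(as.matrix(dist(pts)) + base * (1 - diag(n)))
  })
}

# Scramble TAD orientations of a truth structure about their centroids;
# optionally mirror one TAD.  Returns the list of fragment matrices.
scramble_tads <- function(truth, seed, mirror_tad = NULL) {
  xyz <- chromfold::coords_matrix(truth$structure)
  idx <- split(seq_len(nrow(xyz)), truth$structure$tad)
  withr::with_seed(seed, lapply(seq_along(idx), function(i) {
    f <- xyz[idx[[i]], , drop = FALSE]
    c0 <- colMeans(f)
    R <- chromfold::rotation_matrix(rnorm(3), runif(1, 0, pi))
    out <- sweep(sweep(f, 2, c0) %*% t(R), 2, c0, `+`)
    if (!is.null(mirror_tad) && i == mirror_tad) {
      M <- diag(3)
      M[1, 1] <- -1
      out <- sweep(sweep(out, 2, c0) %*% t(M), 2, c0, `+`)
    }
    out
  }))
}

true_junction_distances <- function(truth) {
  xyz <- chromfold::coords_matrix(truth$structure)
  idx <- split(seq_len(nrow(xyz)), truth$structure$tad)
  n <- length(idx)
  vapply(seq_len(n - 1), function(i) {
    e_i <- xyz[idx[[i]][length(idx[[i]])], ]
    s_next <- xyz[idx[[i + 1]][1], ]
    sqrt(sum((s_next - e_i)^2))
  }, numeric(1))
}
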