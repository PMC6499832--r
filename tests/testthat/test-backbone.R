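test_that("neighbour affinities normalise over ordered off-diagonal pairs", {
  f <- matrix(1, 3, 3)
  diag(f) <- 0
  P <- hic_affinity(contact_map(f))
  expect_equal(P[1, 2], 1 / 6)
  expect_equal(sum(P), 1)

  f2 <- matrix(0, 3, 3)
  f2[1, 2] <- f2[2, 1] <- 5
  P2 <- hic_affinity(contact_map(f2))
  expect_equal(P2[1, 2], 1 / 2)
  expect_equal(P2[2, 1], 1 / 2)

  expect_error(hic_affinity(contact_map(matrix(0, 3, 3))), "signal")

  for (seed in 1:5) {
    expect_equal(sum(hic_affinity(random_contacts(5, seed))), 1,
                 tolerance = 1e-12)
  }
})

test_that("embedding probabilities normalise and respect symmetry", {
  # n = 2: both ordered pairs get 1/2 regardless of positions
  q2 <- embedding_prob(matrix(c(0, 0, 0, 3, 1, 2), 2, 3, byrow = TRUE))
  expect_equal(q2[1, 2], 0.5)
  # equilateral triangle: all six ordered pairs equal
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(unique(round(embedding_prob(tri)[upper.tri(diag(3))], 12)),
               1 / 6)
  for (seed in 1:5) {
    expect_equal(sum(embedding_prob(random_coords(4, seed))), 1,
                 tolerance = 1e-12)
  }
})

test_that("KL cost: zero iff P equals Q, hand-computed value, positivity", {
  Q <- matrix(1 / 6, 3, 3)
  diag(Q) <- 0
  expect_equal(kl_cost(Q, Q), 0)

  # all mass on one symmetric pair vs uniform: 2 * 1/2 * log(3) = log 3
  P <- matrix(0, 3, 3)
  P[1, 2] <- P[2, 1] <- 1 / 2
  expect_equal(kl_cost(P, Q), log(3), tolerance = 1e-12)

  for (seed in 1:100) {
    P <- hic_affinity(random_contacts(4, seed))
    Q <- embedding_prob(random_coords(4, seed + 1000))
    expect_gte(kl_cost(P, Q), 0)
  }
})

test_that("FISH cost closed form and missing-entry handling", {
  fm <- fish_dist(matrix(c(0, 1, 1, 0), 2))
  conf <- rbind(c(0, 0, 0), c(2, 0, 0))
  fc <- fish_cost(conf, fm)
  # ordered double count: 2 * (2 - 1)^2
  expect_equal(fc$cost, 2)

  exact <- rbind(c(0, 0, 0), c(1, 0, 0))
  fc2 <- fish_cost(exact, fm)
  expect_equal(fc2$cost, 0)
  expect_equal(max(abs(fc2$gradient)), 0)

  # fully missing FISH matrix contributes no cost
  fm_na <- fish_dist(matrix(c(0, NA, NA, 0), 2))
  expect_equal(fish_cost(conf, fm_na)$cost, 0)
})

test_that("KL, FISH and combined backbone gradients match finite differences", {
  for (seed in 1:5) {
    x <- random_coords(6, seed)
    P <- hic_affinity(random_contacts(6, seed + 50))
    fm <- random_fish(6, seed + 100)

    kg <- chromfold:::kl_cost_grad(x, P)
    expect_lt(max_rel_diff(
      kg$gradient,
      fd_gradient(function(z) chromfold:::kl_cost_grad(z, P)$cost, x)),
      1e-5)

    fg <- fish_cost(x, fm)
    expect_lt(max_rel_diff(
      fg$gradient, fd_gradient(function(z) fish_cost(z, fm)$cost, x)),
      1e-5)

    bg <- backbone_cost(x, P, fm, lambda_E = 0.3, lambda_F = 0.7,
                        polymer = polymer_params(rest_length = 0.5))
    expect_lt(max_rel_diff(
      bg$gradient,
      fd_gradient(function(z) backbone_cost(z, P, fm, 0.3, 0.7,
        polymer_params(rest_length = 0.5))$cost, x)),
      1e-5)
  }
})

test_that("backbone cost is invariant under rigid motions", {
  x <- random_coords(8, 11)
  P <- hic_affinity(random_contacts(8, 12))
  fm <- random_fish(8, 13)
  base <- backbone_cost(x, P, fm, lambda_E = 0.2, lambda_F = 0.5)
  for (seed in 1:5) {
    moved <- random_rigid_motion(x, seed)
    bc <- backbone_cost(moved, P, fm, lambda_E = 0.2, lambda_F = 0.5)
    expect_lt(abs(bc$cost - base$cost), 1e-9 * max(abs(base$cost), 1))
  }
})

test_that("with zero weights the backbone objective reduces to the KL term", {
  x <- random_coords(5, 21)
  P <- hic_affinity(random_contacts(5, 22))
  bc <- backbone_cost(x, P, lambda_E = 0, lambda_F = 0)
  expect_equal(bc$cost, chromfold:::kl_cost_grad(x, P)$cost)
  expect_equal(unname(bc$terms["C2"]), 0)
})

test_that("the optimizer is monotone, seeded, and honours max_iter = 0", {
  truth <- simulate_structure(n_tads = 8, beads_per_tad = 1, seed = 5)
  fm <- simulate_fish(truth, seed = 5)
  cm <- simulate_hic(truth$backbone, seed = 5)

  fit <- fit_backbone(cm, fm, lambda_E = 0.001, lambda_F = 1,
                      opt = optimizer_config(seed = 9, max_iter = 500,
                                             learning_rate = 0.02))
  expect_true(all(diff(fit$trajectory) <= 1e-12))
  expect_lte(tail(fit$trajectory, 1), fit$trajectory[1])

  fit2 <- fit_backbone(cm, fm, lambda_E = 0.001, lambda_F = 1,
                       opt = optimizer_config(seed = 9, max_iter = 500,
                                              learning_rate = 0.02))
  expect_identical(coords_matrix(fit$conformation),
                   coords_matrix(fit2$conformation))

  init_only <- fit_backbone(cm, fm, lambda_E = 0.001, lambda_F = 1,
                            opt = optimizer_config(seed = 9, max_iter = 0))
  expect_equal(init_only$iterations, 0)
  expect_length(init_only$trajectory, 1)
})

test_that("strong FISH weighting recovers a known 4-point geometry", {
  # brute-force distance fit: with exact distances the global minimum of
  # the FISH stress is the true shape, so the fitted model must match it
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.4, 1.1, 0), c(0.2, 0.5, 0.9))
  fm <- fish_dist(as.matrix(dist(xyz)))
  cm <- simulate_hic(xyz)
  fit <- fit_backbone(cm, fm, lambda_E = 0, lambda_F = 100,
                      opt = optimizer_config(seed = 2, max_iter = 5000,
                                             learning_rate = 0.005))
  al <- align_procrustes(fit$conformation, xyz)
  expect_lt(al$rmsd / radius_of_gyration(xyz), 0.02)
})

test_that("a missing FISH matrix with lambda_F > 0 names the C3 term", {
  cm <- random_contacts(4, 3)
  expect_error(fit_backbone(cm, fish = NULL, lambda_E = 0, lambda_F = 1),
               "C3")
})

test_that("fit objects expose tidy, glance and autoplot", {
  truth <- simulate_structure(n_tads = 6, beads_per_tad = 1, seed = 4)
  fit <- fit_backbone(simulate_hic(truth$backbone), simulate_fish(truth),
                      lambda_E = 0.001, lambda_F = 1,
                      opt = optimizer_config(seed = 1, max_iter = 200))
  td <- tidy(fit)
  expect_true(all(c("x", "y", "z") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_points, 6)
  expect_true(all(c("C1", "C3", "lambda_F") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
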