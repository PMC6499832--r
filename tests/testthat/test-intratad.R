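test_that("radius of gyration closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(-1, 0, 0), c(1, 0, 0))), 1)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(0.5))
})

test_that("radius of gyration is rigid-motion invariant", {
  x <- random_coords(15, 31)
  rg <- radius_of_gyration(x)
  for (seed in 1:5) {
    expect_lt(abs(radius_of_gyration(random_rigid_motion(x, seed)) - rg),
              1e-12 * rg)
  }
})

test_that("Rg constraint cost closed form and subgradient", {
  two <- rbind(c(-1, 0, 0), c(1, 0, 0))
  rc <- rg_cost(two, sqrt(0.25))
  expect_equal(rc$cost, 0.75)

  sat <- rg_cost(two, 1)
  expect_equal(sat$cost, 0)
  expect_equal(max(abs(sat$gradient)), 0)   # sign(0) = 0

  for (seed in 1:5) {
    x <- random_coords(8, seed)
    target <- radius_of_gyration(x) * 1.5   # away from the kink
    rc <- rg_cost(x, target)
    fd <- fd_gradient(function(z) rg_cost(z, target)$cost, x)
    expect_lt(max_rel_diff(rc$gradient, fd), 1e-5)
  }
})

test_that("target Rg estimation follows the ideal-chain conversion", {
  expect_equal(estimate_target_rg(8, list(c = 1, beta = 1 / 3)),
               2 / sqrt(6))
  expect_error(estimate_target_rg(0, list(c = 1, beta = 1 / 3)),
               "positive")
  # vectorised over TAD lengths
  expect_equal(estimate_target_rg(c(8, 64), list(c = 1, beta = 1 / 3)),
               c(2, 4) / sqrt(6))
})

test_that("intra-TAD gradients match finite differences", {
  for (seed in 1:5) {
    x <- random_coords(7, seed)
    P <- hic_affinity(random_contacts(7, seed + 10))
    target <- radius_of_gyration(x) * 1.4
    tc <- tad_cost(x, P, target, lambda_E = 0.2, lambda_R = 0.6,
                   polymer = polymer_params(rest_length = 0.5))
    fd <- fd_gradient(function(z) tad_cost(z, P, target, 0.2, 0.6,
      polymer_params(rest_length = 0.5))$cost, x)
    expect_lt(max_rel_diff(tc$gradient, fd), 1e-5)
  }
})

test_that("optimizing only the Rg term shrinks C4 monotonically", {
  x0 <- random_coords(10, 44, sd = 2)
  target <- radius_of_gyration(x0) / 3
  P <- hic_affinity(random_contacts(10, 45))
  fn <- function(z) {
    rc <- rg_cost(z, target)
    list(cost = rc$cost, gradient = rc$gradient)
  }
  res <- chromfold:::gd_minimize(x0, fn,
                                 optimizer_config(learning_rate = 0.05,
                                                  max_iter = 300))
  expect_true(all(diff(res$trajectory) <= 1e-12))
  expect_lt(res$cost, fn(x0)$cost / 100)
})

test_that("a strong Rg constraint pins the fitted TAD radius", {
  truth <- simulate_structure(n_tads = 2, beads_per_tad = 30, seed = 2)
  frag <- coords_matrix(truth$structure)[truth$structure$tad == 1, ]
  rg_true <- radius_of_gyration(frag)
  cm <- simulate_hic(frag)
  fit <- fit_tad(cm, target_rg = rg_true, lambda_E = 0.001, lambda_R = 50,
                 opt = optimizer_config(seed = 2, max_iter = 5000,
                                        learning_rate = 0.005))
  rg_fit <- radius_of_gyration(fit$conformation)
  expect_lt(abs(rg_fit - rg_true) / rg_true, 0.05)
})

test_that("with zero weights fit_tad reduces to the KL-only embedding and is seeded", {
  cm <- random_contacts(8, 6)
  f1 <- fit_tad(cm, lambda_E = 0, lambda_R = 0,
                opt = optimizer_config(seed = 7, max_iter = 100))
  expect_equal(unname(f1$terms[c("C2", "C4")]), c(0, 0))
  f2 <- fit_tad(cm, lambda_E = 0, lambda_R = 0,
                opt = optimizer_config(seed = 7, max_iter = 100))
  expect_identical(coords_matrix(f1$conformation),
                   coords_matrix(f2$conformation))
})

test_that("per-TAD seeds make fit_all_tads order-independent and reproducible", {
  truth <- simulate_structure(n_tads = 3, beads_per_tad = 8, seed = 9)
  inputs <- simulate_inputs(truth, seed = 9)
  fits <- fit_all_tads(inputs$intra_contacts, target_rgs = c(.1, .1, .1),
                       lambda_E = 0.001, lambda_R = 5,
                       opt = optimizer_config(seed = 3, max_iter = 100))
  # refitting TAD 2 alone with its derived seed gives the identical model
  solo <- fit_tad(inputs$intra_contacts[[2]], target_rg = 0.1,
                  lambda_E = 0.001, lambda_R = 5,
                  opt = optimizer_config(seed = 5, max_iter = 100))
  expect_identical(coords_matrix(fits[[2]]$conformation),
                   coords_matrix(solo$conformation))
})
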