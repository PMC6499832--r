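test_that("power-law fit recovers exact (c, beta) from noiseless data", {
  tads <- tad_set("chr1", start = (0:9) * 1e5, end = (1:10) * 1e5)
  g <- chromfold:::tad_genomic_separation(tads)
  fm <- fish_dist(2 * g^0.3 * (1 - diag(10)) + diag(0, 10))
  pl <- fit_distance_powerlaw(fm, tads)
  expect_equal(pl$c, 2, tolerance = 1e-9)
  expect_equal(pl$beta, 0.3, tolerance = 1e-9)

  # constant distances give beta = 0
  fm2 <- fish_dist(1.5 * (1 - diag(10)))
  pl2 <- fit_distance_powerlaw(fm2, tads)
  expect_equal(pl2$beta, 0, tolerance = 1e-9)

  # too few usable pairs
  small <- tad_set("chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  fm3 <- fish_dist(matrix(c(0, 1, 1, 0), 2))
  expect_error(fit_distance_powerlaw(fm3, small), "3 usable")
})

test_that("linker distance closed forms", {
  p <- assembly_params(alpha_exponent = -0.25, c = 1, beta = 1 / 3)
  expect_equal(linker_distance(16, 1000, p), 0.5)
  expect_equal(linker_distance(1, 1000, p), 1)
  expect_equal(linker_distance(0, 8, p), 2)
  expect_equal(linker_distance(c(16, 0), c(1000, 8), p), c(0.5, 2))
  expect_error(linker_distance(-1, 10, p), ">= 0")
  expect_error(linker_distance(0, 0, p), "positive genomic")
})

test_that("integration cost closed forms and finite-difference gradient", {
  # junction gaps exactly at target: zero cost
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  f2 <- rbind(c(2, 0, 0), c(3, 0, 0))
  expect_equal(integration_cost(list(f1, f2), 1)$cost, 0)

  # single junction, gap 2, target 1: cost 1, gradient magnitude 2
  f3 <- rbind(c(3, 0, 0), c(4, 0, 0))
  ic <- integration_cost(list(f1, f3), 1)
  expect_equal(ic$cost, 1)
  expect_equal(ic$junction_grad[1, ], c(2, 0, 0))

  # random 4-TAD instance vs finite differences on all endpoints
  for (seed in 1:5) {
    frags <- lapply(1:4, function(i) random_coords(3, seed * 10 + i))
    d <- abs(rnorm(3)) + 0.5
    ic <- integration_cost(frags, d)
    for (j in 1:3) {
      fn_s <- function(z) {
        fr <- frags
        fr[[j + 1]][1, ] <- z[1, ]
        integration_cost(fr, d)$cost
      }
      fd <- fd_gradient(fn_s, frags[[j + 1]][1, , drop = FALSE])
      expect_lt(max_rel_diff(ic$junction_grad[j, , drop = FALSE], fd),
                1e-5)
    }
  }
})

test_that("rotate_tad_step performs the capped Rodrigues rotation rigidly", {
  frag <- rbind(c(1, 0, 0), c(0.5, 0.2, -0.1), c(-0.3, 0.1, 0.4))
  centre <- c(0, 0, 0)

  # target at the current endpoint: identity
  same <- rotate_tad_step(frag, centre, 1, c(1, 0, 0))
  expect_equal(same, frag)

  # 90 degrees about +z
  rot <- rotate_tad_step(rbind(c(1, 0, 0), c(0.2, 0.1, 0)), centre, 1,
                         c(0, 1, 0))
  expect_equal(rot[1, ], c(0, 1, 0), tolerance = 1e-12)

  # collinear target: axis undefined, no rotation
  col <- rotate_tad_step(frag, centre, 1, c(2, 0, 0))
  expect_equal(col, frag)

  # rigid: pairwise distances and centre preserved
  for (seed in 1:5) {
    f <- random_coords(6, seed)
    c0 <- colMeans(f)
    tgt <- rnorm(3)
    out <- rotate_tad_step(f, c0, 1, tgt)
    expect_lt(max(abs(as.matrix(dist(out)) - as.matrix(dist(f)))), 1e-9)
    expect_lt(max(abs(colMeans(out) - c0)), 1e-9)
  }
})

test_that("assembly translates centroids, preserves rigidity, monotone cost", {
  truth <- simulate_structure(n_tads = 5, beads_per_tad = 20, seed = 3)
  frags <- scramble_tads(truth, seed = 30)
  d <- true_junction_distances(truth)
  asm <- assemble_chromosome(truth$backbone, frags, d = d,
                             params = assembly_params(max_iter = 100,
                                                      learning_rate = 0.2))
  expect_true(all(diff(asm$trajectory) <= 1e-12))
  bb <- coords_matrix(truth$backbone)
  out <- coords_matrix(asm$conformation)
  for (i in 1:5) {
    blk <- out[asm$conformation$tad == i, ]
    expect_lt(max(abs(colMeans(blk) - bb[i, ])), 1e-9)
    expect_lt(max(abs(as.matrix(dist(blk)) -
                        as.matrix(dist(frags[[i]])))), 1e-9)
    expect_true(abs(det(asm$placements$rotation[[i]]) - 1) < 1e-9)
  }
})

test_that("pre-oriented TADs with matching gaps are left unchanged", {
  truth <- simulate_structure(n_tads = 4, beads_per_tad = 10, seed = 8)
  xyz <- coords_matrix(truth$structure)
  idx <- split(seq_len(nrow(xyz)), truth$structure$tad)
  frags <- lapply(idx, function(ii) xyz[ii, ])
  d <- true_junction_distances(truth)
  asm <- assemble_chromosome(truth$backbone, frags, d = d,
                             params = assembly_params(max_iter = 50))
  expect_equal(asm$cost, 0, tolerance = 1e-20)
  expect_equal(coords_matrix(asm$conformation), xyz, tolerance = 1e-9)
})

test_that("reflection resolves a constructed antipodal junction trap", {
  # TAD 2's start endpoint points exactly away from TAD 1's end, so the
  # rotation axis is undefined and rotations alone cannot close the gap;
  # the mirror trial can
  f1 <- rbind(c(-5.5, 0, 0), c(-4.5, 0, 0))
  f2 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  backbone <- conformation(rbind(c(-5, 0, 0), c(0, 0, 0)))
  on <- assemble_chromosome(backbone, list(f1, f2), d = 1,
                            params = assembly_params(max_iter = 30,
                                                     try_reflection = TRUE))
  off <- assemble_chromosome(backbone, list(f1, f2), d = 1,
                             params = assembly_params(max_iter = 30,
                                                      try_reflection = FALSE))
  expect_lt(on$cost, off$cost)
  expect_true(any(on$placements$reflected))
})

test_that("junction inputs are read from the full-resolution map", {
  truth <- simulate_structure(n_tads = 3, beads_per_tad = 4, seed = 11)
  inputs <- simulate_inputs(truth, seed = 11)
  ji <- chromfold:::junction_inputs(inputs$full_contacts, rep(4, 3),
                                    truth$tads, resolution = 5000)
  expect_length(ji$f_link, 2)
  full <- unclass(inputs$full_contacts)
  expect_equal(ji$f_link[1], full[4, 5])
  expect_equal(ji$f_link[2], full[8, 9])
  expect_equal(ji$g_link, rep(5000, 2))
  # noiseless counts invert exactly back to distances
  p <- assembly_params(alpha_exponent = -0.25)
  xyz <- coords_matrix(truth$structure)
  expect_equal(linker_distance(ji$f_link, ji$g_link, p),
               c(sqrt(sum((xyz[5, ] - xyz[4, ])^2)),
                 sqrt(sum((xyz[9, ] - xyz[8, ])^2))),
               tolerance = 1e-9)
})
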