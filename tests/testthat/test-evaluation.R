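test_that("relative error closed forms at TAD level", {
  xyz <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  fm <- fish_dist(matrix(c(0, 1, 1, 0), 2))
  re <- relative_error(conformation(xyz), fm)
  expect_equal(re$re[1, 2], 0.2)
  expect_equal(re$mean_re, 0.2)

  exact <- conformation(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(relative_error(exact, fm)$mean_re, 0)
})

test_that("final-mode relative error averages the cross-TAD locus pairs", {
  # 2 TADs x 2 loci; the 4 cross distances enumerated by hand
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0),      # TAD 1
               c(3, 0, 0), c(3, 4, 0))      # TAD 2
  conf <- conformation(xyz, bins = tibble::tibble(tad = c(1, 1, 2, 2)))
  d_cross <- mean(c(3, sqrt(9 + 16), 2, sqrt(4 + 16)))
  fm <- fish_dist(matrix(c(0, 2, 2, 0), 2))
  re <- relative_error(conf, fm, mode = "final")
  expect_equal(re$re[1, 2], abs(d_cross - 2) / 2)
})

test_that("missing FISH entries are excluded from RE averaging", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  fm <- fish_dist(matrix(c(0, 2, NA, 2, 0, 2, NA, 2, 0), 3))
  re <- relative_error(conformation(xyz), fm)
  expect_true(is.na(re$re[1, 3]))
  expect_equal(re$mean_re, mean(c(0.5, abs(sqrt(5) - 2) / 2)))
})

test_that("compartment calling separates two spatial clusters exactly", {
  withr::with_seed(10, {
    a <- matrix(rnorm(30, sd = 0.2), 10, 3)
    b <- sweep(matrix(rnorm(30, sd = 0.2), 10, 3), 2, c(5, 0, 0), `+`)
    xyz <- rbind(a, b)[sample(20), ]
  })
  truth_labels <- ifelse(xyz[, 1] < 2.5, 1L, -1L)
  labels <- call_compartments(conformation(xyz))
  expect_equal(compartment_accuracy(labels, truth_labels), 1)
  # invariant to rigid motion
  moved <- conformation(random_rigid_motion(xyz, 3))
  expect_equal(call_compartments(moved), labels)
})

test_that("degenerate equidistant TADs are flagged but deterministic", {
  simplex <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_warning(l1 <- call_compartments(conformation(simplex)),
                 "degenerate")
  expect_warning(l2 <- call_compartments(conformation(simplex)),
                 "degenerate")
  expect_identical(l1, l2)
  expect_true(all(l1 %in% c(-1L, 1L)))
})

test_that("compartment accuracy is permutation-symmetric", {
  l <- c(1L, 1L, -1L, 1L, -1L)
  expect_equal(compartment_accuracy(l, l), 1)
  expect_equal(compartment_accuracy(l, -l), 1)
  r <- l
  r[1] <- -r[1]
  expect_equal(compartment_accuracy(l, r), 4 / 5)
})

test_that("asphericity: rod 1, cube 0, uniform ball near 0", {
  line <- cbind(seq(0, 1, length.out = 50), 0, 0)
  expect_equal(asphericity(line), 1)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(asphericity(cube), 0)
  withr::with_seed(99, {
    u <- matrix(rnorm(15000), 5000, 3)
    u <- u / sqrt(rowSums(u^2)) * runif(5000)^(1 / 3)
  })
  expect_lt(asphericity(u), 0.02)
  # rigid-motion invariance
  x <- random_coords(40, 5)
  expect_lt(abs(asphericity(random_rigid_motion(x, 8)) - asphericity(x)),
            1e-9)
})

test_that("TAD density scales with genomic length and inversely with volume", {
  withr::with_seed(3, frag <- matrix(rnorm(45), 15, 3))
  d1 <- tad_density(frag, 1e5)
  expect_equal(tad_density(frag, 2e5), 2 * d1)
  expect_equal(tad_density(frag * 2, 1e5), d1 / 8)
  expect_equal(d1, 1e5 / convex_hull_volume(frag))
})

test_that("Hi-C/FISH consistency hits its monotone extremes and null", {
  withr::with_seed(21, pts <- matrix(rnorm(18), 6, 3))
  fm <- fish_dist(as.matrix(dist(pts)))
  f_anti <- contact_map(unclass(fm + diag(6))^-4 - diag(1, 6))
  expect_equal(hic_fish_consistency(f_anti, fm), 1)
  f_mono <- contact_map(unclass(fm)^2)
  expect_equal(hic_fish_consistency(f_mono, fm), 0)

  # independent random inputs sit near 1/2
  withr::with_seed(77, {
    f <- abs(matrix(rnorm(100), 10)) + 0.01
    fr <- contact_map(f)
    fm2 <- random_fish(10, 78)
  })
  n_pairs <- choose(choose(10, 2), 2)
  se <- sqrt(0.25 / n_pairs)
  # pairs of pairs are dependent, allow a generous factor over the iid se
  expect_lt(abs(hic_fish_consistency(fr, fm2) - 0.5), 30 * se)
})

test_that("Procrustes alignment: rigid copies, mirrors, and noise scale", {
  x <- random_coords(25, 14)
  moved <- random_rigid_motion(x, 15)
  expect_lt(align_procrustes(moved, x)$rmsd, 1e-9)

  mirrored <- x %*% diag(c(-1, 1, 1))
  expect_lt(align_procrustes(mirrored, x)$rmsd, 1e-9)

  withr::with_seed(16, {
    sigma <- 0.05
    noisy <- x + matrix(rnorm(75, sd = sigma), 25, 3)
  })
  rmsd <- align_procrustes(noisy, x)$rmsd
  expect_gt(rmsd, sigma * sqrt(3) * 0.6)
  expect_lt(rmsd, sigma * sqrt(3) * 1.4)
})

test_that("evaluate_model assembles a coherent report", {
  truth <- simulate_structure(n_tads = 8, beads_per_tad = 6,
                              polarized = TRUE, seed = 12)
  inputs <- simulate_inputs(truth, seed = 12)
  rep <- evaluate_model(truth$structure, inputs$fish, tads = truth$tads,
                        contacts = inputs$tad_contacts,
                        reference_labels = truth$labels)
  gl <- glance(rep)
  expect_equal(gl$n_tads, 8)
  expect_equal(gl$compartment_accuracy, 1)
  expect_equal(gl$hic_fish_consistency, 1)
  expect_true(gl$mean_re >= 0)
  td <- tidy(rep)
  expect_equal(nrow(td), 8 * 7)
  expect_s3_class(autoplot(rep), "ggplot")
})
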