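# Synthetic ground-truth generator.
#
# Emulates the statistical structure of the method's two inputs: a
# chromosome-scale FISH mean-distance table between TADs and Hi-C
# contact maps whose expected counts follow an inverse-power law of
# spatial distance (f ~ d^-4, the inverse of the d = f^-0.25
# contact-to-distance relation).  The geometry is a confined, weakly
# self-avoiding random walk: TAD centres take constant steps of about
# 0.4 µm inside a 1.5 µm sphere (the scale of chromosome territories in
# human fibroblast imaging), and each TAD is a persistent local walk of
# beads around its centre.  Optionally the TADs are split into two
# planted compartment blocks whose walks drift toward opposite
# half-spaces, emulating spatially polarised A/B compartments.

#' Simulate a ground-truth chromosome structure
#'
#' @param n_tads Number of TADs.
#' @param beads_per_tad Bins modelled inside each TAD; with 1 the
#'   structure equals its backbone.
#' @param polarized Plant two spatially separated compartment blocks
#'   (alternating blocks of `block_size` TADs labelled ±1) whose TAD
#'   centres drift toward opposite half-spaces.
#' @param seed Integer seed; the result is reproducible from
#'   `(parameters, seed)`.
#' @param tad_spacing Step length of the TAD-centre walk (µm).
#' @param confinement_radius Radius of the spherical territory (µm).
#' @param tad_radius Confinement radius of each intra-TAD walk (µm).
#' @param bead_step Step length of the intra-TAD walk (µm).
#' @param persistence Directional persistence of the intra-TAD walk in
#'   `[0, 1)`; higher values give more elongated TADs, mimicking the
#'   stiffness of the chromatin fibre at the 5 kb scale.
#' @param block_size TADs per planted compartment block.
#' @param polar_offset Distance of the two compartment attractor points
#'   from the territory centre (µm).
#' @param drift Mixing weight of the attractor direction in the polarised
#'   TAD-centre walk.
#' @param resolution Bin size in bp; each TAD spans
#'   `beads_per_tad * resolution` bp, TADs are genomically adjacent.
#' @param chrom Chromosome name used in the metadata.
#' @return A `chromfold_truth` list: `structure` (full-resolution
#'   conformation with `tad` labels), `backbone` (TAD centroids),
#'   `tads`, `labels` (planted ±1 compartments), `params`, `seed`.
#' @export
simulate_structure <- function(n_tads = 20, beads_per_tad = 25,
                               polarized = FALSE, seed = 1,
                               tad_spacing = 0.4,
                               confinement_radius = 1.5,
                               tad_radius = 0.25, bead_step = 0.07,
                               persistence = 0.8, block_size = 5,
                               polar_offset = 0.75, drift = 0.5,
                               resolution = 5000, chrom = "chrS") {
  stopifnot(n_tads >= 2, beads_per_tad >= 1)
  params <- list(n_tads = n_tads, beads_per_tad = beads_per_tad,
                 polarized = polarized, tad_spacing = tad_spacing,
                 confinement_radius = confinement_radius,
                 tad_radius = tad_radius, bead_step = bead_step,
                 persistence = persistence, block_size = block_size,
                 polar_offset = polar_offset, drift = drift,
                 resolution = resolution, chrom = chrom)
  labels <- planted_labels(n_tads, block_size)
  out <- withr::with_seed(seed, {
    centres <- walk_tad_centres(n_tads, tad_spacing, confinement_radius,
                                if (polarized) labels else NULL,
                                polar_offset, drift)
    frags <- lapply(seq_len(n_tads), function(i) {
      if (beads_per_tad == 1) {
        matrix(centres[i, ], 1, 3)
      } else {
        local_tad_walk(beads_per_tad, centres[i, ], bead_step,
                       tad_radius, persistence)
      }
    })
    list(centres = centres, frags = frags)
  })
  tad_len <- beads_per_tad * resolution
  tads <- tad_set(chrom = chrom,
                  start = (seq_len(n_tads) - 1) * tad_len,
                  end = seq_len(n_tads) * tad_len)
  bins <- bind_rows(lapply(seq_len(n_tads), function(i) {
    tibble(chrom = chrom,
           start = tads$start[i] + (seq_len(beads_per_tad) - 1) *
             resolution,
           end = tads$start[i] + seq_len(beads_per_tad) * resolution,
           tad = i)
  }))
  xyz <- do.call(rbind, out$frags)
  structure(list(
    structure = conformation(xyz, bins),
    backbone = conformation(out$centres, tads),
    tads = tads,
    labels = labels,
    params = params,
    seed = seed),
    class = "chromfold_truth")
}

planted_labels <- function(n_tads, block_size) {
  blocks <- rep(rep(c(1L, -1L), length.out = ceiling(n_tads / block_size)),
                each = block_size)
  blocks[seq_len(n_tads)]
}

# Constant-step confined walk for TAD centres.  In polarised mode each
# label's TADs are confined to their own half-space (with a small margin
# around the partition plane) and the walk drifts toward a per-label
# attractor point, emulating the spatially polarised arrangement of A/B
# compartments seen in chromosome-scale imaging.
walk_tad_centres <- function(n, step, radius, labels, polar_offset,
                             drift, margin = 0.1) {
  centres <- matrix(0, n, 3)
  attractor <- function(i) {
    if (is.null(labels)) return(NULL)
    c(labels[i] * polar_offset, 0, 0)
  }
  in_halfspace <- function(i, pt) {
    is.null(labels) || labels[i] * pt[1] >= margin
  }
  a1 <- attractor(1)
  repeat {
    centres[1, ] <- if (is.null(a1)) {
      random_unit() * runif(1, 0, radius / 2)
    } else {
      a1 + random_unit() * runif(1, 0, radius / 4)
    }
    if (in_halfspace(1, centres[1, ])) break
  }
  min_sep <- 0.5 * step
  for (i in 2:n) {
    att <- attractor(i)
    placed <- FALSE
    for (try in 1:500) {
      dir <- random_unit()
      if (!is.null(att)) {
        pull <- att - centres[i - 1, ]
        npull <- sqrt(sum(pull^2))
        if (npull > 0) dir <- normalize(dir * (1 - drift) +
                                          drift * pull / npull)
      }
      cand <- centres[i - 1, ] + step * dir
      far_enough <- if (i > 2) {
        min(sqrt(rowSums(sweep(centres[seq_len(i - 2), , drop = FALSE],
                               2, cand)^2))) > min_sep
      } else TRUE
      if (sqrt(sum(cand^2)) <= radius && far_enough &&
          in_halfspace(i, cand)) {
        centres[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      # compartment switch from deep inside the other half-space: take a
      # longer linker step straight toward the attractor (inter-block
      # linkers may exceed the within-block spacing)
      back <- if (!is.null(att)) att else c(0, 0, 0)
      dirv <- normalize(back - centres[i - 1, ] + 1e-6 * random_unit())
      len <- step
      repeat {
        cand <- centres[i - 1, ] + len * dirv
        if (in_halfspace(i, cand) || len >= 4 * step) break
        len <- len + step
      }
      centres[i, ] <- cand
    }
  }
  centres
}

# Persistent constant-step walk confined to a ball around `centre`,
# recentred so its centroid equals `centre`.
local_tad_walk <- function(n_beads, centre, step, radius, persistence) {
  xyz <- matrix(0, n_beads, 3)
  dir <- random_unit()
  for (i in 2:n_beads) {
    for (try in 1:100) {
      prop <- normalize(persistence * dir +
                          (1 - persistence) * random_unit())
      cand <- xyz[i - 1, ] + step * prop
      if (sqrt(sum(cand^2)) <= radius) {
        xyz[i, ] <- cand
        dir <- prop
        break
      }
      # bounce: bias back toward the TAD centre
      dir <- normalize(dir - 1.5 * normalize(xyz[i - 1, ]))
    }
    if (all(xyz[i, ] == 0) && i > 1) {
      xyz[i, ] <- xyz[i - 1, ] + step * normalize(-xyz[i - 1, ] +
                                                    1e-6 * random_unit())
    }
  }
  sweep(xyz, 2, centre - colMeans(xyz), `+`)
}

random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) c(1, 0, 0) else v / n
}

#' Simulate a Hi-C contact map from a structure
#'
#' Expected counts follow the inverse-power contact-to-distance law
#' `f_ij = count_scale * d_ij^exponent` (default exponent -4, the
#' inverse of the `d = f^-0.25` relation), optionally Poisson-sampled.
#'
#' @param conf Conformation tibble, coordinate matrix, or
#'   `chromfold_truth` (whose full-resolution structure is used).
#' @param exponent Distance exponent (negative).
#' @param count_scale Multiplicative count scale.
#' @param noise `"none"` for expected counts, `"poisson"` for sampled
#'   counts.
#' @param seed Seed used for Poisson sampling.
#' @param min_distance Floor (µm) applied to distances before the power
#'   law, so coincident points cannot produce infinite counts.
#' @return A `contact_map`.
#' @export
simulate_hic <- function(conf, exponent = -4, count_scale = 1,
                         noise = c("none", "poisson"), seed = 1,
                         min_distance = 1e-6) {
  noise <- match.arg(noise)
  stopifnot(exponent < 0)
  if (inherits(conf, "chromfold_truth")) conf <- conf$structure
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  D <- pmax(pairwise_distances(xyz), min_distance)
  f <- count_scale * D^exponent
  diag(f) <- 0
  if (noise == "poisson") {
    f <- withr::with_seed(seed, {
      ut <- upper.tri(f)
      counts <- rpois(sum(ut), f[ut])
      f[ut] <- counts
      f[lower.tri(f)] <- t(f)[lower.tri(f)]
      f
    })
  }
  contact_map(f, resolution = "simulated")
}

#' Simulate a FISH mean-distance matrix from a structure
#'
#' Exact pairwise TAD-centre distances plus optional truncated Gaussian
#' noise; a fraction of entries can be masked as missing.
#'
#' @param truth A `chromfold_truth`, or a backbone conformation/matrix.
#' @param noise_sd Gaussian noise standard deviation (µm).
#' @param missing_frac Fraction of TAD pairs masked `NA`.
#' @param seed Seed.
#' @return A `fish_dist` matrix.
#' @export
simulate_fish <- function(truth, noise_sd = 0, missing_frac = 0,
                          seed = 1) {
  conf <- if (inherits(truth, "chromfold_truth")) truth$backbone else truth
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  D <- pairwise_distances(xyz)
  m <- nrow(D)
  D <- withr::with_seed(seed, {
    if (noise_sd > 0) {
      ut <- upper.tri(D)
      noisy <- D[ut] + rnorm(sum(ut), sd = noise_sd)
      bad <- noisy <= 0
      for (it in 1:100) {
        if (!any(bad)) break
        noisy[bad] <- D[ut][bad] + rnorm(sum(bad), sd = noise_sd)
        bad <- noisy <= 0
      }
      noisy[bad] <- 1e-6
      D[ut] <- noisy
      D[lower.tri(D)] <- t(D)[lower.tri(D)]
    }
    if (missing_frac > 0) {
      ut_idx <- which(upper.tri(D))
      n_mask <- round(missing_frac * length(ut_idx))
      mask <- sample(ut_idx, n_mask)
      D[mask] <- NA
      D <- (function(M) { M[lower.tri(M)] <- t(M)[lower.tri(M)]; M })(D)
    }
    D
  })
  fish_dist(D)
}

#' Simulate the full input bundle for a reconstruction run
#'
#' @param truth A `chromfold_truth` from [simulate_structure()].
#' @param count_scale,exponent,noise Passed to [simulate_hic()].
#' @param fish_noise_sd,fish_missing_frac Passed to [simulate_fish()].
#' @param seed Seed for the stochastic components.
#' @return List with `tad_contacts` (TAD-level map from backbone
#'   distances), `full_contacts` (bin-level map), `intra_contacts`
#'   (per-TAD bin-level maps), `fish`, and the `truth` itself.
#' @export
simulate_inputs <- function(truth, count_scale = 1, exponent = -4,
                            noise = "none", fish_noise_sd = 0,
                            fish_missing_frac = 0, seed = 1) {
  stopifnot(inherits(truth, "chromfold_truth"))
  tad_contacts <- simulate_hic(truth$backbone, exponent = exponent,
                               count_scale = count_scale, noise = noise,
                               seed = seed)
  full_contacts <- simulate_hic(truth$structure, exponent = exponent,
                                count_scale = count_scale, noise = noise,
                                seed = seed + 1L)
  idx <- split(seq_len(nrow(truth$structure)), truth$structure$tad)
  intra_contacts <- lapply(idx, function(ii) {
    contact_map(unclass(full_contacts)[ii, ii, drop = FALSE],
                resolution = truth$params$resolution)
  })
  fish <- simulate_fish(truth, noise_sd = fish_noise_sd,
                        missing_frac = fish_missing_frac,
                        seed = seed + 2L)
  list(tad_contacts = tad_contacts, full_contacts = full_contacts,
       intra_contacts = intra_contacts, fish = fish,
       tads = truth$tads, labels = truth$labels, truth = truth)
}

#' Write a simulated bundle to disk in the package's text formats
#'
#' @param inputs Result of [simulate_inputs()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_contact_map(inputs$tad_contacts, file.path(dir,
                                                   "tad_contacts.txt"))
  write_contact_map(inputs$full_contacts, file.path(dir,
                                                    "full_contacts.txt"))
  for (i in seq_along(inputs$intra_contacts)) {
    write_contact_map(inputs$intra_contacts[[i]],
                      file.path(dir, sprintf("intra_tad_%03d.txt", i)))
  }
  write_fish_matrix(inputs$fish, file.path(dir, "fish.csv"))
  write_tads(inputs$truth$tads, file.path(dir, "tads.bed"))
  write_conformation(inputs$truth$structure,
                     file.path(dir, "truth_structure.csv"))
  write_conformation(inputs$truth$backbone,
                     file.path(dir, "truth_backbone.csv"))
  readr::write_csv(tibble(tad = seq_along(inputs$truth$labels),
                          label = inputs$truth$labels),
                   file.path(dir, "truth_labels.csv"))
  invisible(dir)
}
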