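# Low-level 3D geometry helpers shared across the fitting, assembly and
# evaluation code.  Coordinates are always n x 3 matrices in micrometres.

#' Extract the coordinate matrix of a conformation
#'
#' @param conf A conformation tibble with numeric columns `x`, `y`, `z`.
#' @return An n x 3 numeric matrix.
#' @export
coords_matrix <- function(conf) {
  stopifnot(all(c("x", "y", "z") %in% names(conf)))
  m <- as.matrix(conf[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

pairwise_distances <- function(xyz) {
  as.matrix(dist(xyz))
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis Length-3 vector; need not be normalised.
#' @param angle Rotation angle in radians.
#' @return A 3 x 3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) {
    return(diag(3))
  }
  k <- axis / nrm
  kx <- matrix(c(0, k[3], -k[2],
                 -k[3], 0, k[1],
                 k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

# Reflection through the plane with unit normal `n` passing through the
# origin: I - 2 n n'.
reflection_matrix <- function(normal) {
  nrm <- sqrt(sum(normal^2))
  if (nrm < .Machine$double.eps) {
    # degenerate normal: reflect through the yz-plane for determinism
    normal <- c(1, 0, 0)
    nrm <- 1
  }
  n <- normal / nrm
  diag(3) - 2 * tcrossprod(n)
}

# Apply a 3x3 linear map about a centre point to an n x 3 coordinate block.
transform_about <- function(xyz, linear, centre) {
  sweep(sweep(xyz, 2, centre) %*% t(linear), 2, centre, `+`)
}

#' Volume of the convex hull of a 3D point set
#'
#' Computes the exact volume of the convex hull by an incremental hull
#' construction (tetrahedron seed, visible-facet deletion, horizon
#' re-triangulation), then sums signed tetrahedra against an interior point.
#' Degenerate (coplanar or collinear) inputs have zero volume and trigger a
#' warning.
#'
#' @param xyz An n x 3 coordinate matrix (or a conformation tibble).
#' @return The hull volume (micrometres cubed); 0 with a warning for
#'   degenerate inputs.
#' @export
convex_hull_volume <- function(xyz) {
  if (is.data.frame(xyz)) xyz <- coords_matrix(xyz)
  xyz <- unique(xyz)
  n <- nrow(xyz)
  if (n < 4) {
    warn("fewer than 4 distinct points: hull volume is 0")
    return(0)
  }
  scale <- max(abs(xyz - matrix(colMeans(xyz), n, 3, byrow = TRUE)))
  if (scale == 0) {
    warn("all points coincide: hull volume is 0")
    return(0)
  }
  tol <- 1e-10 * scale
  hull <- tryCatch(build_hull3d(xyz, tol), error = function(e) NULL)
  if (is.null(hull)) {
    warn("degenerate (coplanar/collinear) point set: hull volume is 0")
    return(0)
  }
  interior <- colMeans(xyz)
  vol <- 0
  for (f in hull) {
    a <- xyz[f[1], ] - interior
    b <- xyz[f[2], ] - interior
    c <- xyz[f[3], ] - interior
    vol <- vol + det(cbind(a, b, c)) / 6
  }
  abs(vol)
}

# Incremental 3D convex hull.  Returns a list of integer triples (facets)
# with consistent outward orientation.  Errors if no non-degenerate seed
# tetrahedron exists.
build_hull3d <- function(xyz, tol) {
  n <- nrow(xyz)
  seed <- find_seed_tetrahedron(xyz, tol)
  centre <- colMeans(xyz[seed, ])
  facets <- list()
  for (tri in list(seed[c(1, 2, 3)], seed[c(1, 2, 4)],
                   seed[c(1, 3, 4)], seed[c(2, 3, 4)])) {
    facets[[length(facets) + 1]] <- orient_facet(tri, xyz, centre)
  }
  remaining <- setdiff(seq_len(n), seed)
  for (p in remaining) {
    pt <- xyz[p, ]
    visible <- vapply(facets, function(f) {
      facet_signed_dist(f, xyz, pt) > tol
    }, logical(1))
    if (!any(visible)) next
    # horizon = directed edges of visible facets whose reverse is not visible
    vis_facets <- facets[visible]
    edges <- do.call(rbind, lapply(vis_facets, function(f) {
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    facets <- facets[!visible]
    for (e in seq_len(nrow(horizon))) {
      facets[[length(facets) + 1]] <- c(horizon[e, 1], horizon[e, 2], p)
    }
  }
  facets
}

find_seed_tetrahedron <- function(xyz, tol) {
  n <- nrow(xyz)
  i1 <- 1
  d <- rowSums(sweep(xyz, 2, xyz[i1, ])^2)
  i2 <- which.max(d)
  if (sqrt(d[i2]) <= tol) abort("degenerate point set")
  ab <- xyz[i2, ] - xyz[i1, ]
  # farthest from the line i1-i2
  ap <- sweep(xyz, 2, xyz[i1, ])
  cross_norms <- vapply(seq_len(n), function(i) {
    v <- c(ab[2] * ap[i, 3] - ab[3] * ap[i, 2],
           ab[3] * ap[i, 1] - ab[1] * ap[i, 3],
           ab[1] * ap[i, 2] - ab[2] * ap[i, 1])
    sqrt(sum(v^2))
  }, numeric(1))
  i3 <- which.max(cross_norms)
  if (cross_norms[i3] / sqrt(sum(ab^2)) <= tol) abort("collinear point set")
  nrm <- pracma_cross(ab, xyz[i3, ] - xyz[i1, ])
  plane_d <- abs(ap %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(plane_d)
  if (plane_d[i4] <= tol) abort("coplanar point set")
  c(i1, i2, i3, i4)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orient_facet <- function(tri, xyz, interior) {
  if (facet_signed_dist(tri, xyz, interior) > 0) tri[c(1, 3, 2)] else tri
}

facet_signed_dist <- function(tri, xyz, pt) {
  a <- xyz[tri[1], ]
  nrm <- pracma_cross(xyz[tri[2], ] - a, xyz[tri[3], ] - a)
  sum(nrm * (pt - a)) / sqrt(sum(nrm^2))
}

# Numerically robust centroid/radius-of-gyration helpers.
centroid <- function(xyz) colMeans(xyz)

#' Radius of gyration of a point set
#'
#' \eqn{R_g^2 = \frac{1}{N} \sum_i \lVert y_i - \bar y \rVert^2}: the
#' root-mean-square distance of the points from their centroid.
#'
#' @param conf A conformation tibble or an n x 3 coordinate matrix.
#' @return Non-negative scalar (micrometres).
#' @export
radius_of_gyration <- function(conf) {
  xyz <- if (is.data.frame(conf)) coords_matrix(conf) else conf
  if (nrow(xyz) == 0) abort("empty conformation")
  sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
}
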