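# broom-style tidiers and ggplot2 autoplot methods for the fitted
# objects, so results drop straight into dplyr/ggplot2 workflows.

#' @describeIn fit_backbone Per-point coordinates of a fit as a tibble.
#' @param x A `chromfold_fit`.
#' @param ... Unused.
#' @export
tidy.chromfold_fit <- function(x, ...) {
  as_tibble(x$conformation)
}

#' @describeIn fit_backbone One-row fit summary: final cost, individual
#'   terms, weights, iterations, convergence flag.
#' @export
glance.chromfold_fit <- function(x, ...) {
  out <- tibble(kind = x$kind,
                cost = tail(x$trajectory, 1),
                iterations = x$iterations,
                converged = x$converged,
                n_points = nrow(x$conformation))
  for (nm in names(x$terms)) out[[nm]] <- unname(x$terms[nm])
  for (nm in names(x$lambda)) out[[nm]] <- unname(x$lambda[nm])
  out
}

#' @describeIn assemble_chromosome Assembled per-point coordinates with
#'   TAD labels and per-TAD reflection flags.
#' @param x A `chromfold_assembly`.
#' @param ... Unused.
#' @export
tidy.chromfold_assembly <- function(x, ...) {
  dplyr::left_join(as_tibble(x$conformation),
                   x$placements[, c("tad", "reflected")], by = "tad")
}

#' @describeIn assemble_chromosome One-row assembly summary.
#' @export
glance.chromfold_assembly <- function(x, ...) {
  tibble(cost = x$cost,
         sweeps = length(x$trajectory) - 1,
         n_tads = nrow(x$placements),
         n_points = nrow(x$conformation),
         n_reflected = sum(x$placements$reflected))
}

#' @describeIn tune_lambda The per-grid-point score table.
#' @param x A `chromfold_tune`.
#' @param ... Unused.
#' @export
tidy.chromfold_tune <- function(x, ...) {
  x$table
}

#' @describeIn tune_lambda The best grid point as a one-row tibble.
#' @export
glance.chromfold_tune <- function(x, ...) {
  x$best
}

#' @describeIn evaluate_model The relative-error matrix in long form.
#' @param x A `chromfold_report`.
#' @param ... Unused.
#' @export
tidy.chromfold_report <- function(x, ...) {
  m <- x$re
  tibble(tad_i = rep(seq_len(nrow(m)), ncol(m)),
         tad_j = rep(seq_len(ncol(m)), each = nrow(m)),
         re = as.vector(m)) |>
    filter(.data$tad_i != .data$tad_j)
}

#' @describeIn evaluate_model The one-row metric summary.
#' @export
glance.chromfold_report <- function(x, ...) {
  x$summary
}

#' @describeIn fit_backbone Cost trajectory plot of a fit.
#' @param object The object to plot.
#' @export
autoplot.chromfold_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$trajectory) - 1,
               cost = object$trajectory)
  ggplot(df, aes(x = .data$iteration, y = .data$cost)) +
    geom_line() +
    labs(title = sprintf("%s fit: cost trajectory", object$kind),
         x = "iteration", y = "cost") +
    theme_minimal()
}

#' @describeIn assemble_chromosome Integration-cost trajectory plot.
#' @export
autoplot.chromfold_assembly <- function(object, ...) {
  df <- tibble(sweep = seq_along(object$trajectory) - 1,
               cost = object$trajectory)
  ggplot(df, aes(x = .data$sweep, y = .data$cost)) +
    geom_line() + geom_point() +
    labs(title = "assembly: integration cost per sweep",
         x = "sweep", y = "integration cost") +
    theme_minimal()
}

#' @describeIn evaluate_model Heatmap of the relative-error matrix.
#' @export
autoplot.chromfold_report <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$tad_i, y = .data$tad_j, fill = .data$re)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "firebrick",
                         na.value = "grey85") +
    coord_equal() +
    labs(title = "relative error vs FISH distances",
         x = "TAD", y = "TAD", fill = "RE") +
    theme_minimal()
}

#' Plot the projections of a conformation
#'
#' Three 2D projections (xy, xz, yz) of a model, points connected in
#' genomic order and coloured by TAD when a `tad` column is present.
#'
#' @param conf A conformation tibble.
#' @return A ggplot object.
#' @export
plot_conformation <- function(conf) {
  proj <- bind_rows(
    mutate(conf, h = .data$x, v = .data$y, panel = "xy"),
    mutate(conf, h = .data$x, v = .data$z, panel = "xz"),
    mutate(conf, h = .data$y, v = .data$z, panel = "yz"))
  p <- ggplot(proj, aes(x = .data$h, y = .data$v)) +
    facet_wrap(~panel) +
    coord_equal() +
    labs(x = NULL, y = NULL, colour = "TAD") +
    theme_minimal()
  if ("tad" %in% names(conf)) {
    p + geom_path(aes(colour = factor(.data$tad))) +
      geom_point(aes(colour = factor(.data$tad)), size = 0.8)
  } else {
    p + geom_path() + geom_point(size = 0.8)
  }
}
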