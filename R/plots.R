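# ggplot2 visualizations: mesh layout, SED histograms (the semi-log
# dressing-vs-control comparison), reduction reports, solution fields and
# indentation curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mesh colored by region
#'
#' @param mesh A 2-D `fea_mesh`.
#' @param displacement Optional nodal displacement matrix to draw the
#'   deformed configuration.
#' @return A ggplot.
#' @export
plot_mesh <- function(mesh, displacement = NULL) {
  stopifnot(mesh$dim == 2L)
  X <- mesh$nodes
  if (!is.null(displacement)) X <- X + displacement
  e <- mesh$elements
  df <- tibble::tibble(
    id = rep(seq_len(nrow(e)), each = 4L),
    region = rep(mesh$region, each = 4L),
    x = X[as.vector(t(e)), 1],
    y = X[as.vector(t(e)), 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, fill = .data$region)) +
    ggplot2::geom_polygon(color = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fea_mesh <- function(object, ...) plot_mesh(object, ...)

#' Contour-style plot of a solution field on the deformed mesh
#'
#' @param object An `fea_solution`.
#' @param field `"sed"` or `"distortional"` (von Mises), kPa.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fea_solution <- function(object, field = c("sed", "distortional"),
                                  ...) {
  field <- match.arg(field)
  m <- object$mesh
  X <- m$nodes + displacement_field(object)
  e <- m$elements
  vals <- if (field == "sed") object$sed else
    distortional_stress_field(object)$distortional_stress
  df <- tibble::tibble(
    id = rep(seq_len(nrow(e)), each = 4L),
    value = rep(vals, each = 4L),
    x = X[as.vector(t(e)), 1],
    y = X[as.vector(t(e)), 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$id, fill = .data$value)) +
    ggplot2::geom_polygon() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = if (field == "sed") "SED (kPa)" else
                    "von Mises (kPa)") +
    ggplot2::theme_minimal()
}

#' Semi-log SED histogram plot
#'
#' Volume (fraction) of soft tissue per SED bin on a log y scale; pass a
#' named list of histograms to overlay dressing and control curves.
#'
#' @param object A `sed_histogram`, or a named list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sed_histogram <- function(object, ...) {
  plot_sed_histograms(list(histogram = object))
}

#' @rdname autoplot.sed_histogram
#' @param histograms Named list of `sed_histogram`s.
#' @export
plot_sed_histograms <- function(histograms) {
  df <- purrr::imap_dfr(histograms, function(h, nm) {
    tibble::tibble(case = nm, mid = h$mid, volume = h$volume)
  })
  ggplot2::ggplot(dplyr::filter(df, .data$volume > 0),
                  ggplot2::aes(x = .data$mid, y = .data$volume,
                               color = .data$case)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "strain energy density (kPa)",
                  y = "tissue volume per bin",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of percent SED reductions per dressing
#'
#' @param object A `reduction_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reduction_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "dressing", total = "reduction_total_pct",
                  `< 0.5 kPa` = "reduction_low_pct",
                  `>= 0.5 kPa` = "reduction_high_pct"),
    -"dressing", names_to = "pool", values_to = "reduction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dressing, y = .data$reduction,
                                   fill = .data$pool)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "% SED reduction vs no dressing",
                  fill = "pool") +
    ggplot2::theme_minimal()
}

#' Plot indentation load-displacement curves
#'
#' @param curves Long-format curve tibble (see
#'   [generate_indentation_curves()]).
#' @return A ggplot.
#' @export
plot_indentation_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$displacement, y = .data$force,
                               group = interaction(.data$location,
                                                   .data$replicate),
                               color = factor(.data$location))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "displacement (mm)", y = "force (N)",
                  color = "location") +
    ggplot2::theme_minimal()
}
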