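# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a finite-element solution into a per-element tibble
#'
#' @param x An `fea_solution`.
#' @param ... Unused.
#' @return A tibble with element index, region, centroid coordinates,
#'   reference volume, SED (kPa) and von Mises stress (kPa).
#' @export
tidy.fea_solution <- function(x, ...) {
  m <- x$mesh
  e <- m$elements
  cx <- rowMeans(matrix(m$nodes[e, 1], ncol = ncol(e)))
  cy <- rowMeans(matrix(m$nodes[e, 2], ncol = ncol(e)))
  # pull fields out before tibble() so the `x`/`y` columns cannot mask the
  # solution object in the sequential column evaluation
  vol <- x$element_volume
  sed <- x$sed
  vm <- distortional_stress_field(x)$distortional_stress
  tibble::tibble(
    element = seq_len(nrow(e)),
    region = m$region,
    x = cx, y = cy,
    volume = vol,
    sed_kpa = sed,
    von_mises_kpa = vm)
}

#' One-row summary of a finite-element solution
#'
#' @param x An `fea_solution`.
#' @param ... Unused.
#' @return A tibble with convergence, size, driving displacement,
#'   mattress-base reaction and peak tissue SED.
#' @export
glance.fea_solution <- function(x, ...) {
  f <- reaction_force(x, "mattress_base")
  tis <- x$mesh$region == "tissue"
  tibble::tibble(
    converged = x$converged,
    nodes = nrow(x$mesh$nodes),
    elements = nrow(x$mesh$elements),
    newton_iterations = x$iterations,
    displacement_mm = x$displacement_magnitude %||% NA_real_,
    reaction_x_n = unname(f["x"]),
    reaction_y_n = unname(f["y"]),
    reaction_magnitude_n = sqrt(sum(f^2)),
    peak_tissue_sed_kpa = max(x$sed[tis]))
}

#' Tidy a SED histogram
#'
#' @param x A `sed_histogram`.
#' @param ... Unused.
#' @return The bin tibble plus under/over-range rows flagged in `range`.
#' @export
tidy.sed_histogram <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(lo = NA_real_, hi = x$lo[1], mid = NA_real_,
                   volume = attr(x, "under"), range = "under"),
    dplyr::mutate(tibble::as_tibble(x), range = "in"),
    tibble::tibble(lo = x$hi[nrow(x)], hi = NA_real_, mid = NA_real_,
                   volume = attr(x, "over"), range = "over"))
}

#' Tidy / summarize an effective-modulus fit
#'
#' @param x An `effective_modulus`.
#' @param ... Unused.
#' @return A one-row tibble of the identified modulus and fit diagnostics.
#' @export
tidy.effective_modulus <- function(x, ...) {
  tibble::tibble(modulus_kpa = x$modulus, slope_n_per_mm = x$slope,
                 r_squared = x$fit_quality,
                 window_lo_mm = x$fit_window[1],
                 window_hi_mm = x$fit_window[2],
                 thickness_mm = x$thickness, correction = x$correction)
}

#' @rdname tidy.effective_modulus
#' @export
glance.effective_modulus <- function(x, ...) tidy.effective_modulus(x)

#' @export
print.pooled_auc <- function(x, ...) {
  cat(sprintf("<pooled_auc> threshold %.2f kPa\n", x$threshold))
  cat(sprintf("  auc_low %.4g, auc_high %.4g, total %.4g (volume x kPa)\n",
              x$auc_low, x$auc_high, x$auc_total))
  invisible(x)
}

#' Tidy a pooled AUC
#'
#' @param x A `pooled_auc`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.pooled_auc <- function(x, ...) {
  tibble::tibble(auc_low = x$auc_low, auc_high = x$auc_high,
                 auc_total = x$auc_total, vol_low = x$vol_low,
                 vol_high = x$vol_high, threshold = x$threshold)
}
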