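# Flat-punch indentation analysis: effective dressing modulus from
# load-displacement curves, with a bonded-layer correction, and the
# conservative minimum-selection rule across replicates.

#' Flat-punch probe specification
#'
#' @param diameter Punch diameter, mm (default 6).
#' @param compression_rate Displacement rate, mm/s (default 1; quasi-static
#'   analysis, recorded for provenance only).
#' @param peak_displacement_fraction Peak displacement as a fraction of the
#'   initial sample thickness (default 0.5 = 50% compression).
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(diameter = 6, compression_rate = 1,
                       peak_displacement_fraction = 0.5) {
  stopifnot(diameter > 0, compression_rate > 0,
            peak_displacement_fraction > 0, peak_displacement_fraction <= 1)
  structure(list(diameter = diameter, compression_rate = compression_rate,
                 peak_displacement_fraction = peak_displacement_fraction),
            class = "probe_spec")
}

#' Bonded-layer stiffness correction for a flat punch
#'
#' Correction factor `kappa(a/t) >= 1` multiplying the half-space flat-punch
#' stiffness for a layer of thickness `t` bonded to a rigid substrate:
#' `kappa = 1 + 1.33 (a/t) + 1.33 (a/t)^3` (confined-layer polynomial form).
#' Values are tabulated on a fine grid and interpolated. `mode = "none"`
#' returns 1 (half-space analysis).
#'
#' @param a_over_t Punch radius over layer thickness (>= 0).
#' @param mode `"bonded"` (default) or `"none"`.
#' @return Correction factor(s).
#' @export
layer_correction_kappa <- function(a_over_t, mode = c("bonded", "none")) {
  mode <- match.arg(mode)
  if (any(a_over_t < 0)) stop("a/t must be >= 0", call. = FALSE)
  if (mode == "none") return(rep(1, length(a_over_t)))
  grid <- seq(0, 5, by = 0.01)
  tab <- 1 + 1.33 * grid + 1.33 * grid^3
  if (any(a_over_t > max(grid))) {
    stop("a/t beyond tabulated range (punch much wider than layer)",
         call. = FALSE)
  }
  stats::approx(grid, tab, xout = a_over_t)$y
}

#' Effective modulus from a flat-punch indentation curve
#'
#' Fits the initial slope `k = dF/d(delta)` over a compression window
#' (default 5-25% of thickness, avoiding toe-region seating artifacts and
#' large-strain stiffening), then inverts the bonded-layer flat-punch
#' relation `F = 2 a kappa(a/t) E/(1 - nu^2) delta` for the effective
#' Young's modulus.
#'
#' @param curve A tibble with `displacement` (mm, monotone non-decreasing,
#'   starting at 0), `force` (N) and a `thickness` column (mm), as produced
#'   by [generate_indentation_curves()] or [read_indentation_curves()].
#' @param probe A [probe_spec()].
#' @param poisson Foam Poisson ratio (default 0.1).
#' @param window Compression window (fractions of thickness) for the fit.
#' @param correction `"bonded"` layer correction or `"none"` (half-space).
#' @return An object of class `effective_modulus`: list with `modulus`
#'   (kPa), `fit_window` (mm), `fit_quality` (R^2), `slope` (N/mm), `n`.
#' @export
effective_modulus_from_curve <- function(curve, probe = probe_spec(),
                                         poisson = 0.1,
                                         window = c(0.05, 0.25),
                                         correction = c("bonded", "none")) {
  correction <- match.arg(correction)
  stopifnot(all(c("displacement", "force", "thickness") %in% names(curve)))
  d <- curve$displacement
  f <- curve$force
  t <- curve$thickness[1]
  if (t <= 0) stop("sample thickness must be > 0", call. = FALSE)
  if (length(d) != length(f)) stop("unequal sample arrays", call. = FALSE)
  if (is.unsorted(d)) stop("displacement must be monotone non-decreasing",
                           call. = FALSE)
  if (abs(d[1]) > 1e-12) stop("displacement must start at 0", call. = FALSE)
  sel <- d >= window[1] * t & d <= window[2] * t
  if (sum(sel) < 5L) {
    stop("sampling error: fewer than 5 samples in the fit window",
         call. = FALSE)
  }
  fit <- stats::lm(f[sel] ~ d[sel])
  k <- unname(stats::coef(fit)[2])
  sst <- sum((f[sel] - mean(f[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 0
  if (!is.finite(k) || k <= 0) {
    stop("data-quality error: non-increasing force in the fit window",
         call. = FALSE)
  }
  a <- probe$diameter / 2
  kap <- layer_correction_kappa(a / t, correction)
  # k [N/mm] -> E [kPa]: N/mm^2 = MPa = 1e3 kPa
  E <- k * (1 - poisson^2) / (2 * a * kap) * 1e3
  structure(list(modulus = E, fit_window = window * t, fit_quality = r2,
                 slope = k, n = sum(sel), thickness = t,
                 correction = correction, poisson = poisson),
            class = "effective_modulus")
}

#' @export
print.effective_modulus <- function(x, ...) {
  cat(sprintf("<effective_modulus> E = %.3f kPa (R^2 = %.4f, window %.2f-%.2f mm, %s)\n",
              x$modulus, x$fit_quality, x$fit_window[1], x$fit_window[2],
              x$correction))
  invisible(x)
}

#' Effective moduli for a set of indentation curves
#'
#' Applies [effective_modulus_from_curve()] to every
#' (dressing, location, replicate) curve of a long-format curve table.
#'
#' @inheritParams effective_modulus_from_curve
#' @param curves Long-format curve tibble (see
#'   [generate_indentation_curves()]).
#' @return A tibble with one row per curve: identifiers, `modulus_kpa`,
#'   `fit_quality`.
#' @export
effective_moduli <- function(curves, probe = probe_spec(), poisson = 0.1,
                             window = c(0.05, 0.25),
                             correction = c("bonded", "none")) {
  correction <- match.arg(correction)
  curves |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("dressing", "location",
                                                  "replicate")))) |>
    dplyr::group_modify(function(g, key) {
      r <- effective_modulus_from_curve(g, probe, poisson, window, correction)
      tibble::tibble(modulus_kpa = r$modulus, fit_quality = r$fit_quality)
    }) |>
    dplyr::ungroup()
}

#' Conservative modulus: the minimum over all replicates
#'
#' The model is run conservatively with the lowest modulus observed across
#' all probed locations and dressings of a type.
#'
#' @param results A numeric vector of moduli, a tibble with a `modulus_kpa`
#'   column, or a list of `effective_modulus` objects.
#' @return The minimum modulus, kPa.
#' @examples
#' conservative_modulus(c(21.3, 19.0, 24.8)) # 19.0
#' @export
conservative_modulus <- function(results) {
  vals <- if (is.numeric(results)) {
    results
  } else if (is.data.frame(results)) {
    results$modulus_kpa
  } else {
    vapply(results, function(r) r$modulus, numeric(1))
  }
  if (!length(vals)) stop("empty result list", call. = FALSE)
  min(vals)
}

#' Read indentation curves from a delimited text file
#'
#' Expects columns `dressing`, `location`, `replicate`, `thickness`,
#' `displacement`, `force` (CSV with a header), the format written by
#' [write_indentation_curves()].
#'
#' @param path Input path.
#' @return A long-format curve tibble.
#' @export
read_indentation_curves <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_indentation_curves
#' @param curves Curve tibble to write.
#' @export
write_indentation_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}
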