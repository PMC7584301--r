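# Biomechanical quantification: SED and distortional-stress fields,
# volume-weighted histograms, damage-threshold pooling and the
# percent-SED-reduction comparison across dressings.

#' Per-element strain energy density of a converged solution
#'
#' Evaluates the constitutive energy density from each element's converged
#' deformation (volume-averaged over quadrature points), restricted to one
#' region. SED is the injury-risk surrogate: total elastic energy stored per
#' unit tissue volume.
#'
#' @param solution An `fea_solution`.
#' @param region Region label, default `"tissue"`.
#' @return Tibble with `element` (index into the mesh), `sed` (kPa) and
#'   `volume` (reference mm^3 per unit depth in 2-D).
#' @export
sed_field <- function(solution, region = "tissue") {
  stopifnot(inherits(solution, "fea_solution"))
  idx <- which(solution$mesh$region == region)
  if (!length(idx)) stop("region '", region, "' not present in the mesh",
                         call. = FALSE)
  tibble::tibble(element = idx, sed = solution$sed[idx],
                 volume = solution$element_volume[idx])
}

#' Von Mises (distortional) equivalent stress per element
#'
#' The scalar measure of the deviatoric, shape-changing part of the Cauchy
#' stress. `measure = "tresca"` gives twice the maximum shear stress
#' instead.
#'
#' @param solution An `fea_solution`.
#' @param region Optional region label to restrict to (default all).
#' @param measure `"von_mises"` (default) or `"tresca"`.
#' @return Tibble with `element` and `distortional_stress` (kPa).
#' @export
distortional_stress_field <- function(solution, region = NULL,
                                      measure = c("von_mises", "tresca")) {
  stopifnot(inherits(solution, "fea_solution"))
  measure <- match.arg(measure)
  S <- solution$stress
  idx <- if (is.null(region)) seq_len(nrow(S)) else
    which(solution$mesh$region == region)
  s11 <- S[idx, "s11"]; s22 <- S[idx, "s22"]
  s12 <- S[idx, "s12"]; s33 <- S[idx, "s33"]
  val <- if (measure == "von_mises") {
    sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) + 3 * s12^2)
  } else {
    # principal stresses: two in-plane roots and s33
    c1 <- (s11 + s22) / 2
    c2 <- sqrt(((s11 - s22) / 2)^2 + s12^2)
    p1 <- c1 + c2; p2 <- c1 - c2
    pmax(p1, p2, s33) - pmin(p1, p2, s33)
  }
  tibble::tibble(element = idx, distortional_stress = val)
}

#' Volume-weighted histogram of an element field
#'
#' Each element's volume accrues to the bin containing its SED value; bins
#' are half-open `[lo, hi)` with the last bin closed. Volume falling below
#' or above the binned range is tracked separately so that total volume is
#' conserved.
#'
#' @param sed Per-element SED values, kPa.
#' @param volumes Per-element volumes (mm^3, or mm^2 per unit depth), all
#'   >= 0.
#' @param edges Strictly increasing bin edges, kPa. Default: 0.05-wide bins
#'   on the analysed range 0.05-1.0 kPa.
#' @param normalization `"volume"` (absolute) or `"fraction"` (of total).
#' @return An object of class `sed_histogram`: a tibble of bins (`lo`, `hi`,
#'   `mid`, `volume`) with attributes `under`, `over`, `total_volume`,
#'   `normalization`.
#' @export
volume_weighted_histogram <- function(sed, volumes,
                                      edges = sed_bin_edges(),
                                      normalization = c("volume",
                                                        "fraction")) {
  normalization <- match.arg(normalization)
  stopifnot(length(sed) == length(volumes))
  if (any(volumes < 0)) stop("negative element volume", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  nb <- length(edges) - 1L
  # half-open [lo, hi), last bin closed
  bin <- findInterval(sed, edges, rightmost.closed = TRUE)
  under <- sum(volumes[bin == 0L])
  over <- sum(volumes[bin > nb])
  keep <- bin >= 1L & bin <= nb
  vols <- numeric(nb)
  if (any(keep)) {
    agg <- rowsum(volumes[keep], bin[keep])
    vols[as.integer(rownames(agg))] <- agg
  }
  total <- sum(volumes)
  scale <- if (normalization == "fraction" && total > 0) total else 1
  out <- tibble::tibble(lo = edges[-length(edges)], hi = edges[-1],
                        mid = (edges[-length(edges)] + edges[-1]) / 2,
                        volume = vols / scale)
  structure(out, under = under / scale, over = over / scale,
            total_volume = total, normalization = normalization,
            class = c("sed_histogram", class(out)))
}

#' Default SED bin edges
#'
#' 0.05 kPa-wide bins spanning the analysed range `range` (default
#' 0.05-1.0 kPa), chosen so that the 0.5 kPa damage threshold is a bin edge.
#'
#' @param range Numeric length-2, kPa.
#' @param width Bin width, kPa.
#' @return Numeric vector of edges.
#' @export
sed_bin_edges <- function(range = c(0.05, 1.0), width = 0.05) {
  seq(range[1], range[2], by = width)
}

#' Pool a SED histogram into below/at-or-above-threshold AUCs
#'
#' Computes the rectangular area under the volume-vs-SED curve,
#' `sum(bin_volume * bin_width)`, restricted to bins below the damage
#' threshold (`auc_low`) and at-or-above it (`auc_high`). The threshold must
#' coincide with a bin edge.
#'
#' @param hist A `sed_histogram`.
#' @param threshold Damage threshold, kPa (default 0.5).
#' @return An object of class `pooled_auc`: list with `auc_low`, `auc_high`,
#'   `auc_total` (volume x kPa) and the pooled raw volumes `vol_low`,
#'   `vol_high`.
#' @export
pool_auc <- function(hist, threshold = 0.5) {
  stopifnot(inherits(hist, "sed_histogram"))
  edges <- c(hist$lo, hist$hi[nrow(hist)])
  if (!any(abs(edges - threshold) < 1e-12)) {
    stop("alignment error: threshold ", threshold, " kPa is not a bin edge; ",
         "re-bin with edges through the threshold", call. = FALSE)
  }
  w <- hist$hi - hist$lo
  low <- hist$hi <= threshold + 1e-12
  auc_low <- sum(hist$volume[low] * w[low])
  auc_high <- sum(hist$volume[!low] * w[!low])
  structure(list(auc_low = auc_low, auc_high = auc_high,
                 auc_total = auc_low + auc_high,
                 vol_low = sum(hist$volume[low]),
                 vol_high = sum(hist$volume[!low]),
                 threshold = threshold),
            class = "pooled_auc")
}

#' Percent SED reduction of a dressing versus the no-dressing control
#'
#' `((AUC_no_dressing - AUC_dressing) / AUC_no_dressing) * 100`; positive
#' when the dressing reduces the tissue exposure.
#'
#' @param auc_no_dressing Control AUC (> 0).
#' @param auc_dressing Dressing AUC.
#' @return Percent reduction.
#' @examples
#' percent_sed_reduction(100, 75) # 25
#' @export
percent_sed_reduction <- function(auc_no_dressing, auc_dressing) {
  if (!is.numeric(auc_no_dressing) || any(auc_no_dressing <= 0)) {
    stop("undefined reduction: no-dressing AUC must be > 0", call. = FALSE)
  }
  (auc_no_dressing - auc_dressing) / auc_no_dressing * 100
}

# Binning for pooling: 0.05-wide bins starting at the lower end of the
# analysed SED range (0.05 kPa) and extending past the largest observed
# value, so 0.5 kPa is always an edge. Volume below 0.05 kPa is outside the
# analysed distribution and does not contribute to any AUC; without this
# floor the total rectangular AUC would equal bin_width x total volume for
# every case and all total reductions would be identically zero.
pooling_edges <- function(..., width = 0.05, floor = 0.05) {
  hi <- max(0.5, unlist(list(...)), na.rm = TRUE)
  seq(floor, ceiling(hi / width + 1e-9) * width + width, by = width)
}

solution_pooled_auc <- function(solution, region = "tissue",
                                threshold = 0.5, edges = NULL) {
  f <- sed_field(solution, region)
  if (is.null(edges)) edges <- pooling_edges(f$sed)
  h <- volume_weighted_histogram(f$sed, f$volume, edges)
  pool_auc(h, threshold)
}

#' Compare dressing scenarios against the shared no-dressing control
#'
#' Computes, for every dressing solution, the percent SED reduction in
#' total, below-threshold and at-or-above-threshold pools relative to the
#' control. All solutions must be converged; the soft-tissue meshes must
#' have the same topology (same tissue element count).
#'
#' @param control The no-dressing `fea_solution`.
#' @param dressings Named list of `fea_solution`s, one per dressing.
#' @param table A dressing parameter table (see
#'   [packaged_dressing_table()]) supplying stiffness/thickness columns;
#'   matched by name. Optional.
#' @param threshold Damage threshold, kPa.
#' @return A `reduction_report` tibble with one row per dressing: `dressing`,
#'   `foam_stiffness_kpa`, `foam_thickness_mm`, `reduction_total_pct`,
#'   `reduction_low_pct`, `reduction_high_pct`, plus peak-SED diagnostics.
#' @export
compare_dressings <- function(control, dressings, table = NULL,
                              threshold = 0.5) {
  stopifnot(inherits(control, "fea_solution"))
  nct <- sum(control$mesh$region %in% c("tissue", "bone"))
  for (nm in names(dressings)) {
    s <- dressings[[nm]]
    if (!inherits(s, "fea_solution") || !isTRUE(s$converged)) {
      stop("dressing solution '", nm, "' is not a converged fea_solution",
           call. = FALSE)
    }
    if (sum(s$mesh$region %in% c("tissue", "bone")) != nct) {
      stop("comparison error: dressing '", nm, "' was solved on a different ",
           "tissue mesh topology than the control", call. = FALSE)
    }
  }
  fc <- sed_field(control)
  edges <- pooling_edges(fc$sed,
                         unlist(lapply(dressings,
                                       function(s) sed_field(s)$sed)))
  pc <- solution_pooled_auc(control, threshold = threshold, edges = edges)
  rows <- purrr::imap(dressings, function(s, nm) {
    p <- solution_pooled_auc(s, threshold = threshold, edges = edges)
    tibble::tibble(
      dressing = nm,
      reduction_total_pct = percent_sed_reduction(pc$auc_total, p$auc_total),
      reduction_low_pct = percent_sed_reduction(pc$auc_low, p$auc_low),
      reduction_high_pct = if (pc$auc_high > 0)
        percent_sed_reduction(pc$auc_high, p$auc_high) else NA_real_,
      peak_sed_kpa = max(sed_field(s)$sed),
      control_peak_sed_kpa = max(fc$sed))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(table)) {
    tb <- dplyr::select(table, dressing = 1,
                        foam_stiffness_kpa = dplyr::any_of("foam_stiffness_kpa"),
                        foam_thickness_mm = dplyr::any_of("foam_thickness_mm"))
    out <- dplyr::left_join(out, tb, by = "dressing")
    out <- dplyr::relocate(out, dressing, foam_stiffness_kpa,
                           foam_thickness_mm)
  }
  structure(out, threshold = threshold,
            class = c("reduction_report", class(out)))
}

#' Write a reduction report as a comma-delimited table
#'
#' Column headers mirror the published table schema exactly
#' (`Dressing`, `Foam stiffness (kPa)`, `Foam thickness (mm)`,
#' `% SED reduction in total`, `% SED reduction of <0.5 kPa`,
#' `% SED reduction of >=0.5 kPa`).
#'
#' @param report A `reduction_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reduction_report <- function(report, path) {
  out <- tibble::tibble(
    `Dressing` = report$dressing,
    `Foam stiffness (kPa)` = report$foam_stiffness_kpa %||%
      rep(NA_real_, nrow(report)),
    `Foam thickness (mm)` = report$foam_thickness_mm %||%
      rep(NA_real_, nrow(report)),
    `% SED reduction in total` = report$reduction_total_pct,
    `% SED reduction of <0.5 kPa` = report$reduction_low_pct,
    `% SED reduction of >=0.5 kPa` = report$reduction_high_pct)
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a solution field for external contour visualization
#'
#' Writes the full 2-D section (plane `"sagittal"`) as a legacy VTK
#' unstructured grid with the requested cell field. Field values are
#' exported in MPa (the kPa-to-MPa conversion is applied on export only, to
#' mirror conventional contour-plot axis units).
#'
#' @param solution An `fea_solution`.
#' @param path Output `.vtk` path.
#' @param plane `"sagittal"` (the 2-D section). `"axial"` is only
#'   meaningful for 3-D solutions and errors in 2-D mode.
#' @param field `"sed"` or `"distortional"`.
#' @return `path`, invisibly.
#' @export
export_contour <- function(solution, path, plane = c("sagittal", "axial"),
                           field = c("sed", "distortional")) {
  plane <- match.arg(plane)
  field <- match.arg(field)
  if (plane == "axial" && solution$mesh$dim == 2L) {
    stop("mode error: axial plane is undefined for a 2-D sagittal model",
         call. = FALSE)
  }
  vals <- if (field == "sed") solution$sed else
    distortional_stress_field(solution)$distortional_stress
  cd <- list()
  cd[[paste0(field, "_MPa")]] <- vals / 1000
  write_vtk(solution$mesh, path,
            point_data = list(displacement = displacement_field(solution)),
            cell_data = cd)
  invisible(path)
}
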