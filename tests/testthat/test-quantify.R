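# a minimal synthetic solved state for quantification tests
fake_solution <- function(sed, volumes, stress = NULL, region = "tissue") {
  ne <- length(sed)
  mesh <- structured_grid(ne, 1, ne, 1)
  mesh$region <- rep(region, ne)
  if (is.null(stress)) {
    stress <- matrix(0, ne, 4, dimnames = list(NULL, c("s11", "s22", "s12",
                                                       "s33")))
  }
  structure(list(mesh = mesh, u = numeric(2L * nrow(mesh$nodes)),
                 sed = sed, stress = stress, element_volume = volumes,
                 converged = TRUE, materials = list()),
            class = "fea_solution")
}

test_that("sed_field evaluates the constitutive energy of the converged state", {
  # undeformed: identically zero
  cc0 <- confined_column(1 - 1e-12, ny = 3)
  f0 <- foamfea:::element_fields(cc0$mesh, list(tissue = tissue_material()),
                                 numeric(2L * nrow(cc0$mesh$nodes)))
  expect_equal(max(abs(f0$sed)), 0)
  # homogeneous confined compression: every element at W(F) exactly
  cc <- confined_column(0.9, ny = 4)
  mats <- list(tissue = tissue_material())
  flds <- foamfea:::element_fields(cc$mesh, mats, cc$sol$u)
  W <- strain_energy_density(diag(c(1, 0.9)), mats$tissue)
  expect_equal(flds$sed, rep(W, nrow(cc$mesh$elements)), tolerance = 1e-6)
  # region restriction
  sol <- fake_solution(c(1, 2, 3), c(1, 1, 1))
  expect_error(sed_field(sol, "bone"), "not present")
  expect_equal(sed_field(sol, "tissue")$sed, c(1, 2, 3))
})

test_that("distortional stress reproduces closed-form states", {
  hydro <- matrix(rep(c(5, 5, 0, 5), each = 1), 1, 4)
  uni <- matrix(c(7, 0, 0, 0), 1, 4)
  shear <- matrix(c(0, 0, 3, 0), 1, 4)
  colnames(hydro) <- colnames(uni) <- colnames(shear) <-
    c("s11", "s22", "s12", "s33")
  sol <- fake_solution(rep(0, 3), rep(1, 3),
                       stress = rbind(hydro, uni, shear))
  vm <- distortional_stress_field(sol)$distortional_stress
  expect_equal(vm[1], 0, tolerance = 1e-12)
  expect_equal(vm[2], 7, tolerance = 1e-12)
  expect_equal(vm[3], sqrt(3) * 3, tolerance = 1e-12)
  tr <- distortional_stress_field(sol, measure = "tresca")$distortional_stress
  expect_equal(tr[1], 0, tolerance = 1e-12)
  expect_equal(tr[2], 7, tolerance = 1e-12)
  expect_equal(tr[3], 6, tolerance = 1e-12) # principal +-tau, s33 = 0
})

test_that("volume-weighted histogram matches brute-force binning", {
  set.seed(101)
  sed <- stats::runif(1000, 0, 1.2)
  vol <- stats::runif(1000, 0.5, 2)
  edges <- sed_bin_edges()
  h <- volume_weighted_histogram(sed, vol, edges)
  # brute force: per-element scan with half-open bins, last closed
  nb <- length(edges) - 1
  brute <- numeric(nb)
  under <- over <- 0
  for (k in seq_along(sed)) {
    if (sed[k] < edges[1]) {
      under <- under + vol[k]
    } else if (sed[k] > edges[nb + 1]) {
      over <- over + vol[k]
    } else {
      b <- min(which(sed[k] < edges[-1] |
                       (seq_len(nb) == nb & sed[k] <= edges[nb + 1])))
      brute[b] <- brute[b] + vol[k]
    }
  }
  expect_equal(h$volume, brute, tolerance = 1e-12)
  expect_equal(attr(h, "under"), under, tolerance = 1e-12)
  expect_equal(attr(h, "over"), over, tolerance = 1e-12)
  # conservation
  expect_equal(sum(h$volume) + attr(h, "under") + attr(h, "over"),
               sum(vol), tolerance = 1e-9)
})

test_that("histogram handles point masses and input errors", {
  h <- volume_weighted_histogram(rep(0.42, 7), rep(2, 7))
  expect_equal(sum(h$volume > 0), 1L)
  expect_equal(max(h$volume), 14)
  expect_error(volume_weighted_histogram(1, -1), "negative")
  expect_error(volume_weighted_histogram(1, 1, edges = c(1, 0.5)),
               "increasing")
  hf <- volume_weighted_histogram(c(0.1, 0.6), c(1, 3),
                                  normalization = "fraction")
  expect_equal(sum(hf$volume), 1)
})

test_that("pooled AUC equals direct summation and respects the threshold edge", {
  set.seed(7)
  sed <- stats::runif(500, 0, 1.4)
  vol <- stats::runif(500, 0.1, 1)
  edges <- seq(0, 1.5, by = 0.05)
  h <- volume_weighted_histogram(sed, vol, edges)
  p <- pool_auc(h, 0.5)
  w <- 0.05
  direct_low <- sum(vapply(seq_len(length(edges) - 1), function(b) {
    if (edges[b + 1] > 0.5) return(0)
    sum(vol[sed >= edges[b] & sed < edges[b + 1]]) * w
  }, numeric(1)))
  expect_equal(p$auc_low, direct_low, tolerance = 1e-9)
  expect_equal(p$auc_total, p$auc_low + p$auc_high, tolerance = 1e-12)
  # empty high pool
  h2 <- volume_weighted_histogram(rep(0.2, 5), rep(1, 5), edges)
  expect_equal(pool_auc(h2, 0.5)$auc_high, 0)
  # symmetric uniform fill
  h3 <- volume_weighted_histogram(seq(0.025, 0.975, by = 0.05),
                                  rep(2, 20), seq(0, 1, 0.05))
  p3 <- pool_auc(h3, 0.5)
  expect_equal(p3$auc_low, p3$auc_high, tolerance = 1e-12)
  expect_equal(p3$auc_low, 2 * 0.05 * 10, tolerance = 1e-12)
  # misaligned threshold
  expect_error(pool_auc(h, 0.52), "alignment error")
})

test_that("the percent-reduction formula is exact arithmetic", {
  expect_equal(percent_sed_reduction(100, 75), 25)
  expect_equal(percent_sed_reduction(37.19, 24.07),
               (37.19 - 24.07) / 37.19 * 100, tolerance = 1e-12)
  x <- stats::runif(1, 1, 10)
  expect_equal(percent_sed_reduction(x, x), 0)
  expect_error(percent_sed_reduction(0, 1), "undefined")
})

test_that("pool-wise reductions combine exactly into the total reduction", {
  set.seed(33)
  for (i in 1:20) {
    nd <- list(lo = stats::runif(1, 1, 5), hi = stats::runif(1, 1, 5))
    dr <- list(lo = stats::runif(1, 0.1, 5), hi = stats::runif(1, 0.1, 5))
    r_lo <- percent_sed_reduction(nd$lo, dr$lo)
    r_hi <- percent_sed_reduction(nd$hi, dr$hi)
    r_tot <- percent_sed_reduction(nd$lo + nd$hi, dr$lo + dr$hi)
    w_lo <- nd$lo / (nd$lo + nd$hi)
    expect_equal(r_tot, w_lo * r_lo + (1 - w_lo) * r_hi, tolerance = 1e-10)
    expect_gte(r_tot, min(r_lo, r_hi) - 1e-12)
    expect_lte(r_tot, max(r_lo, r_hi) + 1e-12)
  }
})

test_that("compare_dressings reproduces hand-computed rows", {
  set.seed(55)
  ne <- 40
  sed <- stats::runif(ne, 0.06, 1.2)
  vol <- stats::runif(ne, 0.5, 2)
  ctrl <- fake_solution(sed, vol)
  # identical solution: all reductions zero
  same <- compare_dressings(ctrl, list(SAME = fake_solution(sed, vol)))
  expect_equal(same$reduction_total_pct, 0, tolerance = 1e-12)
  expect_equal(same$reduction_low_pct, 0, tolerance = 1e-12)
  expect_equal(same$reduction_high_pct, 0, tolerance = 1e-12)
  # volumes scaled by 0.7 at identical SED values: all reductions 30
  scaled <- compare_dressings(ctrl, list(S = fake_solution(sed, 0.7 * vol)))
  expect_equal(scaled$reduction_total_pct, 30, tolerance = 1e-9)
  expect_equal(scaled$reduction_low_pct, 30, tolerance = 1e-9)
  expect_equal(scaled$reduction_high_pct, 30, tolerance = 1e-9)
  # independent hand calculation of one synthetic pair
  sed2 <- sed * 0.8
  dr <- fake_solution(sed2, vol)
  rep1 <- compare_dressings(ctrl, list(D = dr))
  edges <- foamfea:::pooling_edges(sed, sed2)
  w <- diff(edges)[1]
  auc <- function(s, v, lo, hi) {
    keep <- s >= lo & s < hi & s >= edges[1]
    sum(v[keep]) * w
  }
  acl <- auc(sed, vol, 0, 0.5); ach <- auc(sed, vol, 0.5, Inf)
  adl <- auc(sed2, vol, 0, 0.5); adh <- auc(sed2, vol, 0.5, Inf)
  expect_equal(rep1$reduction_low_pct, (acl - adl) / acl * 100,
               tolerance = 1e-9)
  expect_equal(rep1$reduction_high_pct, (ach - adh) / ach * 100,
               tolerance = 1e-9)
  expect_equal(rep1$reduction_total_pct,
               (acl + ach - adl - adh) / (acl + ach) * 100, tolerance = 1e-9)
  # mismatched meshes refuse to compare
  bad <- fake_solution(stats::runif(10), rep(1, 10))
  expect_error(compare_dressings(ctrl, list(B = bad)), "comparison error")
})

test_that("reduction reports serialize with the published column headers", {
  ctrl <- fake_solution(stats::runif(30, 0.06, 1.2), rep(1, 30))
  dr <- fake_solution(ctrl$sed * 0.8, rep(1, 30))
  rep1 <- compare_dressings(ctrl, list(TSF = dr),
                            table = packaged_dressing_table())
  path <- withr::local_tempfile(fileext = ".csv")
  write_reduction_report(rep1, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "^Dressing,Foam stiffness \\(kPa\\),Foam thickness \\(mm\\)")
  expect_match(hdr, "% SED reduction in total")
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(got$`Foam stiffness (kPa)`, 19.0)
  expect_equal(got$`Foam thickness (mm)`, 5.5)
})

test_that("contour export converts to MPa and round-trips", {
  sol <- fake_solution(c(0.5, 1.5), c(1, 1))
  path <- withr::local_tempfile(fileext = ".vtk")
  export_contour(sol, path, field = "sed")
  vals <- read_vtk_cell_field(path, "sed_MPa")
  expect_equal(vals, c(0.5, 1.5) / 1000, tolerance = 1e-9)
  expect_error(export_contour(sol, path, plane = "axial"), "mode error")
  # zero field stays a valid file
  z <- fake_solution(c(0, 0), c(1, 1))
  export_contour(z, path, field = "distortional")
  expect_equal(read_vtk_cell_field(path, "distortional_MPa"), c(0, 0))
})
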