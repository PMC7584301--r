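test_that("strain energy vanishes at the reference state and under rotation", {
  tis <- tissue_material()
  expect_equal(strain_energy_density(diag(2), tis), 0)
  expect_equal(strain_energy_density(diag(3), tis), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(strain_energy_density(R, tis), 0, tolerance = 1e-12)
  # frame invariance: W(R F) = W(F)
  set.seed(11)
  for (i in 1:10) {
    F <- random_F()
    expect_equal(strain_energy_density(R %*% F, tis),
                 strain_energy_density(F, tis), tolerance = 1e-12)
  }
})

test_that("isochoric closed form matches the energy expression", {
  tis <- tissue_material()
  F <- diag(c(1.1, 1 / 1.1, 1))
  # independent evaluation from the invariants
  I1 <- 1.1^2 + 1 / 1.1^2 + 1
  J <- 1
  cst <- tis$constants
  expect_equal(strain_energy_density(F, tis),
               cst$G / 2 * (I1 - 3) - cst$G * log(J) +
                 cst$lambda / 2 * log(J)^2,
               tolerance = 1e-12)
})

test_that("energy grows without bound as J -> 0+", {
  tis <- tissue_material()
  w <- vapply(c(0.5, 0.1, 0.02, 0.005),
              function(J) strain_energy_density(diag(c(J, 1, 1)), tis),
              numeric(1))
  expect_true(all(diff(w) > 0))
  expect_gt(w[4], 1e3)
  expect_error(strain_energy_density(diag(c(-1, 1, 1)), tis), "inverted")
})

test_that("Cauchy stress is symmetric, zero at rest, hydrostatic for pure dilation", {
  tis <- tissue_material()
  expect_equal(cauchy_stress(diag(2), tis), matrix(0, 3, 3))
  s <- cauchy_stress(1.05 * diag(3), tis)
  expect_equal(s, t(s))
  expect_equal(s[1, 2], 0)
  expect_equal(s[1, 1], s[2, 2], tolerance = 1e-12)
  expect_equal(s[1, 1], s[3, 3], tolerance = 1e-12)
})

test_that("stress is the derivative of the energy (finite differences)", {
  set.seed(21)
  mats <- list(tissue_material(), mattress_material())
  h <- 1e-6
  for (mat in mats) {
    for (rep in 1:5) {
      F <- diag(3)
      F[1:2, 1:2] <- random_F()
      P <- foamfea:::pk1_stress(F, mat)
      for (i in 1:2) for (j in 1:2) {
        Fp <- F; Fp[i, j] <- Fp[i, j] + h
        Fm <- F; Fm[i, j] <- Fm[i, j] - h
        dW <- (strain_energy_density(Fp, mat) -
                 strain_energy_density(Fm, mat)) / (2 * h)
        expect_equal(P[i, j], dW, tolerance = 1e-6)
      }
      # Cauchy: push-forward of P for the hyperelastic family, identical
      # to the small-strain stress for the geometrically linear one
      sig <- cauchy_stress(F, mat)
      if (mat$family == "neo_hookean") {
        expect_equal(sig, P %*% t(F) / det(F), tolerance = 1e-9)
      } else {
        expect_equal(sig, P, tolerance = 1e-12)
      }
    }
  }
})

test_that("material tangent has major symmetry and matches finite differences", {
  set.seed(31)
  h <- 1e-6
  for (mat in list(tissue_material(), mattress_material())) {
    nbad <- 0
    for (rep in 1:100) {
      F <- diag(3)
      F[1:2, 1:2] <- random_F(sd = 0.08)
      A <- material_tangent(F, mat)
      # major symmetry
      expect_equal(A, aperm(A, c(3, 4, 1, 2)), tolerance = 1e-10)
      # spot-check a random component against dP/dF
      i <- sample(1:2, 1); I <- sample(1:2, 1)
      j <- sample(1:2, 1); J <- sample(1:2, 1)
      Fp <- F; Fp[j, J] <- Fp[j, J] + h
      Fm <- F; Fm[j, J] <- Fm[j, J] - h
      fd <- (foamfea:::pk1_stress(Fp, mat)[i, I] -
               foamfea:::pk1_stress(Fm, mat)[i, I]) / (2 * h)
      if (abs(A[i, I, j, J] - fd) >
          1e-5 * max(1, abs(fd))) nbad <- nbad + 1
    }
    expect_equal(nbad, 0)
  }
})

test_that("neo-Hookean tangent at identity equals the linear isotropic tangent", {
  cst <- elastic_constants(E = 50, nu = 0.3)
  Anh <- material_tangent(diag(3), material_neo_hookean(cst))
  Alin <- material_tangent(diag(3), material_linear_elastic(cst))
  expect_equal(Anh, Alin, tolerance = 1e-12)
})

test_that("dressing materials reproduce the effective modulus", {
  tsf <- dressing_material(19.0, 5.50, name = "TSF")
  expect_equal(tsf$constants$E, 19.0)
  expect_equal(tsf$constants$nu, 0.1)
  expect_equal(tsf$solid_fraction, 0.02)
  expect_equal(tsf$thickness, 5.50)
  agb <- dressing_material(30.8, 4.10)
  expect_equal(agb$constants$E, 30.8)
  # a fully solid foam has identical mechanics to the plain neo-Hookean
  solid <- dressing_material(19.0, 5.50, solid_fraction = 1)
  plain <- material_neo_hookean(elastic_constants(E = 19.0, nu = 0.1))
  set.seed(5)
  for (i in 1:5) {
    F <- random_F()
    expect_identical(strain_energy_density(F, solid),
                     strain_energy_density(F, plain))
    expect_identical(cauchy_stress(F, solid), cauchy_stress(F, plain))
  }
  expect_error(dressing_material(-1, 5), "effective_modulus")
  expect_error(dressing_material(19, 0), "thickness")
  expect_error(dressing_material(19, 5, solid_fraction = 0), "solid_fraction")
})
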