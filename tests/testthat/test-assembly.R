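test_that("the reference state is in equilibrium", {
  m <- structured_grid(2, 1, 3, 2)
  m$region[1:3] <- "mattress"
  mats <- list(tissue = tissue_material(), mattress = mattress_material())
  a <- assemble(m, mats, numeric(2L * nrow(m$nodes)))
  expect_equal(max(abs(a$residual)), 0)
})

test_that("a single linear element matches a hand-assembled stiffness", {
  # independent oracle: textbook B-matrix assembly of the plane-strain
  # bilinear quadrilateral at 2x2 Gauss points
  cst <- elastic_constants(E = 100, nu = 0.3)
  D <- with(cst, matrix(c(lambda + 2 * G, lambda, 0,
                          lambda, lambda + 2 * G, 0,
                          0, 0, G), 3, 3, byrow = TRUE))
  X <- rbind(c(0, 0), c(2, 0), c(2.2, 1.1), c(-0.1, 0.9))
  K <- matrix(0, 8, 8)
  g <- 1 / sqrt(3)
  for (xi in c(-g, g)) for (eta in c(-g, g)) {
    dN <- cbind(c(-(1 - eta), 1 - eta, 1 + eta, -(1 + eta)) / 4,
                c(-(1 - xi), -(1 + xi), 1 + xi, 1 - xi) / 4)
    J <- t(dN) %*% X
    dNdX <- dN %*% solve(t(J))
    B <- matrix(0, 3, 8)
    for (a_ in 1:4) {
      B[1, 2 * a_ - 1] <- dNdX[a_, 1]
      B[2, 2 * a_] <- dNdX[a_, 2]
      B[3, 2 * a_ - 1] <- dNdX[a_, 2]
      B[3, 2 * a_] <- dNdX[a_, 1]
    }
    K <- K + t(B) %*% D %*% B * det(J)
  }
  m <- fea_mesh(X, matrix(1:4, 1), "tissue")
  mats <- list(tissue = material_linear_elastic(cst))
  set.seed(7)
  u <- stats::rnorm(8, sd = 0.01)
  a <- assemble(m, mats, u)
  expect_equal(a$residual, as.vector(K %*% u), tolerance = 1e-10)
  expect_equal(as.matrix(a$tangent), K, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the assembled tangent is the derivative of the residual", {
  set.seed(1)
  m <- structured_grid(2, 1, 3, 2)
  m$region[1:3] <- "mattress"
  mats <- list(tissue = tissue_material(), mattress = mattress_material())
  pre <- foamfea:::precompute_fe(m)
  u <- stats::rnorm(pre$ndof, sd = 0.02)
  a <- assemble(m, mats, u, precomp = pre)
  h <- 1e-6
  Kfd <- vapply(seq_along(u), function(k) {
    up <- u; up[k] <- up[k] + h
    um <- u; um[k] <- um[k] - h
    (assemble(m, mats, up, precomp = pre, want_tangent = FALSE)$residual -
       assemble(m, mats, um, precomp = pre,
                want_tangent = FALSE)$residual) / (2 * h)
  }, numeric(pre$ndof))
  expect_lt(max(abs(as.matrix(a$tangent) - Kfd)) / max(abs(Kfd)), 1e-5)
  # energy-based formulation: symmetric without contact
  expect_lt(max(abs(a$tangent - Matrix::t(a$tangent))), 1e-9)
})

test_that("inverted states are rejected with the element identified", {
  m <- structured_grid(1, 1, 1, 1)
  mats <- list(tissue = tissue_material())
  u <- c(0, 0, 0, 0, 0, -2, 0, -2) # top face pushed through the bottom
  expect_error(assemble(m, mats, u), "inverted element")
})

test_that("distorted-mesh patch test is exact for linear materials", {
  set.seed(13)
  m <- structured_grid(4, 4, 5, 5)
  inner <- which(m$nodes[, 1] > 1e-9 & m$nodes[, 1] < 4 - 1e-9 &
                   m$nodes[, 2] > 1e-9 & m$nodes[, 2] < 4 - 1e-9)
  m$nodes[inner, ] <- m$nodes[inner, ] +
    matrix(stats::runif(2 * length(inner), -0.18, 0.18), ncol = 2)
  H <- matrix(c(0.002, 0.001, -0.0005, 0.0015), 2, 2) # uniform grad(u)
  uexact <- m$nodes %*% t(H)
  boundary <- setdiff(seq_len(nrow(m$nodes)), inner)
  bc <- list(dofs = c(2L * boundary - 1L, 2L * boundary),
             values = c(uexact[boundary, 1], uexact[boundary, 2]))

  mats <- list(tissue = material_linear_elastic(
    elastic_constants(E = 50, nu = 0.3)))
  sol <- newton_solve(m, mats, bc, solver_settings(newton_tolerance = 1e-12))
  expect_true(sol$converged)
  expect_equal(sol$iterations, 1L) # linear problem: one Newton step
  u <- matrix(sol$u, ncol = 2, byrow = TRUE)
  expect_equal(u, uexact, tolerance = 1e-10)
  flds <- foamfea:::element_fields(m, mats, sol$u)
  # uniform stress reproduced exactly on every distorted element
  for (k in 1:4) {
    expect_lt(diff(range(flds$stress[, k])), 1e-10)
  }

  # nearly incompressible neo-Hookean at small strain: 1e-8 agreement
  matsnh <- list(tissue = tissue_material())
  solnh <- newton_solve(m, matsnh, bc,
                        solver_settings(newton_tolerance = 1e-12))
  expect_true(solnh$converged)
  fldsnh <- foamfea:::element_fields(m, matsnh, solnh$u)
  for (k in 1:4) {
    expect_lt(diff(range(fldsnh$stress[, k])), 1e-8)
  }
})
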