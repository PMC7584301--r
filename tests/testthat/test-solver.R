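test_that("confined neo-Hookean compression matches the closed form", {
  for (stretch in c(0.9, 0.95)) {
    cc <- confined_column(stretch)
    expect_true(cc$sol$converged)
    R <- sum(cc$sol$r[2L * cc$top])
    P <- confined_closed_form(stretch, cc$constants)
    expect_equal(R, P, tolerance = 1e-6)
    # equilibrium: base reaction balances the top reaction
    expect_equal(sum(cc$sol$r[2L * cc$bot]), -R, tolerance = 1e-6)
  }
})

test_that("symmetric loading produces a symmetric solution", {
  m <- structured_grid(4, 2, 8, 4)
  mats <- list(tissue = tissue_material())
  n <- nrow(m$nodes)
  bot <- which(abs(m$nodes[, 2]) < 1e-9)
  top <- which(abs(m$nodes[, 2] - 2) < 1e-9)
  bc <- list(dofs = c(2L * bot - 1L, 2L * bot, 2L * top),
             values = c(rep(0, 2 * length(bot)), rep(-0.2, length(top))))
  pre <- foamfea:::precompute_fe(m)
  sol <- foamfea:::ramp_solve(m, mats, function(s) {
    b <- bc; b$values <- b$values * s; b
  }, 0, 1, numeric(pre$ndof), NULL, list(), solver_settings(), pre, 4)
  expect_true(sol$converged)
  u <- matrix(sol$u, ncol = 2, byrow = TRUE)
  # mirror each node about x = 2: ux antisymmetric, uy symmetric
  key <- paste(round(m$nodes[, 1], 9), round(m$nodes[, 2], 9))
  mirror <- match(paste(round(4 - m$nodes[, 1], 9),
                        round(m$nodes[, 2], 9)), key)
  expect_lt(max(abs(u[, 1] + u[mirror, 1])), 1e-8)
  expect_lt(max(abs(u[, 2] - u[mirror, 2])), 1e-8)
})

test_that("reactions recover applied tractions and vanish unloaded", {
  m <- structured_grid(2, 1, 1, 1)
  m$sets$left <- which(abs(m$nodes[, 1]) < 1e-9)
  m$sets$right <- which(abs(m$nodes[, 1] - 2) < 1e-9)
  mats <- list(tissue = material_linear_elastic(
    elastic_constants(E = 100, nu = 0.25)))
  left <- m$sets$left
  bc <- list(dofs = c(2L * left - 1L, 2L * left),
             values = rep(0, 2 * length(left)))
  # no load: zero everywhere
  sol0 <- newton_solve(m, mats, bc)
  expect_equal(sqrt(sum(reaction_force(sol0, "left", m)^2)), 0)
  # uniform traction t on the right edge (area = height x unit depth)
  t_mag <- 2 # kPa
  fx <- numeric(2L * nrow(m$nodes))
  fx[2L * m$sets$right - 1L] <- t_mag * 1 / 2 # consistent nodal loads
  sol <- newton_solve(m, mats, bc, f_ext = fx)
  expect_true(sol$converged)
  f <- reaction_force(sol, "left", m)
  # internal units scaled by depth (1 mm) and kPa -> N
  expect_equal(unname(f["x"]), -t_mag * 1 * 1e-3, tolerance = 1e-8)
  expect_error(reaction_force(sol, "nope", m), "unknown surface")
})

test_that("force targeting solves the linear case in one secant pass", {
  # linear-elastic column driven from a fake bone set: reaction = k * d
  m <- structured_grid(1, 10, 1, 6)
  m$depth <- 1000 # report mN as N for easy bookkeeping
  top <- which(abs(m$nodes[, 2] - 10) < 1e-9)
  bot <- which(abs(m$nodes[, 2]) < 1e-9)
  m$sets$bone_surface <- top
  m$sets$mattress_base <- bot
  side <- seq_len(nrow(m$nodes))
  mats <- list(tissue = material_linear_elastic(
    elastic_constants(E = 100, nu = 0)))
  # vertical push (angle 0), target 5 N; column stiffness k = E A / L = 10
  load <- load_case(direction_angle = 0, target_reaction_force = 5,
                    max_displacement_guess = 2)
  sol <- force_targeted_solve(m, mats, load)
  expect_true(sol$converged)
  f <- reaction_force(sol, "mattress_base")
  expect_equal(sqrt(sum(f^2)), 5, tolerance = 0.1)
  expect_equal(sol$displacement_magnitude, 5 / 10, tolerance = 1e-3)
})

test_that("force targeting inverts the confined-compression closed form", {
  m <- structured_grid(1, 10, 1, 6)
  m$depth <- 1000
  n <- nrow(m$nodes)
  top <- which(abs(m$nodes[, 2] - 10) < 1e-9)
  bot <- which(abs(m$nodes[, 2]) < 1e-9)
  m$sets$bone_surface <- top
  m$sets$mattress_base <- bot
  mats <- list(tissue = tissue_material())
  cst <- mats$tissue$constants
  target <- -confined_closed_form(0.9, cst) # compressive reaction, N
  # lateral rollers confine the column so the homogeneous closed form holds
  rollers <- list(dofs = 2L * seq_len(n) - 1L, values = rep(0, n))
  load <- load_case(direction_angle = 0, target_reaction_force = target,
                    max_displacement_guess = 1.5)
  sol <- force_targeted_solve(m, mats, load, extra_bc = rollers)
  expect_true(sol$converged)
  f <- reaction_force(sol, "mattress_base")
  expect_equal(sqrt(sum(f^2)), target, tolerance = 0.1)
  expect_equal(sol$displacement_magnitude, 1, tolerance = 0.02)
})

test_that("an unreachable force target reports the attained force", {
  m <- structured_grid(1, 10, 1, 4)
  m$depth <- 1000
  m$sets$bone_surface <- which(abs(m$nodes[, 2] - 10) < 1e-9)
  m$sets$mattress_base <- which(abs(m$nodes[, 2]) < 1e-9)
  mats <- list(tissue = material_linear_elastic(
    elastic_constants(E = 100, nu = 0)))
  load <- load_case(direction_angle = 0, target_reaction_force = 50,
                    max_displacement_guess = 0.5) # k*d_max = 5 << 50
  expect_error(force_targeted_solve(m, mats, load), "target-unreachable")
})

test_that("element SED is invariant under superposed rigid rotation", {
  cc <- confined_column(0.92, ny = 4)
  mats <- list(tissue = tissue_material())
  sed0 <- foamfea:::element_fields(cc$mesh, mats, cc$sol$u)$sed
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  x <- cc$mesh$nodes + matrix(cc$sol$u, ncol = 2, byrow = TRUE)
  urot <- x %*% t(R) - cc$mesh$nodes
  sed1 <- foamfea:::element_fields(cc$mesh, mats, urot)$sed
  expect_equal(sed1, sed0, tolerance = 1e-9)
})
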