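# Shared fixtures: materials, random deformation states, small contact
# models, and a memoized solve of the packaged reference suite (expensive;
# computed once per test run and reused by the force-target, refinement and
# dressing-comparison tests).

tissue_material <- function() {
  material_neo_hookean(elastic_constants(G = 19.254, K = 1919.022),
                       name = "soft_tissue")
}

mattress_material <- function() {
  material_linear_elastic(elastic_constants(E = 50, nu = 0.3),
                          name = "foam_mattress")
}

# random in-plane deformation gradient with J > 0
random_F <- function(sd = 0.1) {
  repeat {
    F <- diag(2) + matrix(stats::rnorm(4, sd = sd), 2, 2)
    if (det(F) > 0.2) return(F)
  }
}

# stiff block resting on a soft slab with a frictional interface; returns
# everything needed to run press/drag experiments
block_on_slab <- function() {
  slab <- foamfea:::grid_piece(seq(0, 40, 2), seq(0, 5, 2.5), "mattress")
  blk <- foamfea:::grid_piece(seq(15, 25, 2.5), seq(5, 10, 2.5), "dressing")
  nodes <- rbind(slab$nodes, blk$nodes)
  elems <- rbind(slab$elements, blk$elements + nrow(slab$nodes))
  region <- c(slab$region, blk$region)
  eps <- 1e-9
  nsl <- nrow(slab$nodes)
  idx <- seq_len(nrow(nodes))
  sets <- list(
    mattress_base = which(abs(nodes[, 2]) < eps),
    mattress_top = which(abs(nodes[, 2] - 5) < eps & idx <= nsl),
    dressing_bottom = which(abs(nodes[, 2] - 5) < eps & idx > nsl),
    block_top = which(abs(nodes[, 2] - 10) < eps))
  mesh <- fea_mesh(nodes, elems, region, sets, depth = 1)
  list(
    mesh = mesh,
    materials = list(
      mattress = material_linear_elastic(elastic_constants(E = 100,
                                                           nu = 0.3)),
      dressing = material_linear_elastic(elastic_constants(E = 5000,
                                                           nu = 0.3))),
    bc = list(dofs = c(2L * sets$mattress_base - 1L, 2L * sets$mattress_base),
              values = rep(0, 2L * length(sets$mattress_base))),
    top = sets$block_top)
}

# confined-compression column of nearly incompressible tissue: lateral
# rollers force the homogeneous state F = diag(1, stretch)
confined_column <- function(stretch, ny = 10, settings = NULL) {
  m <- structured_grid(1, 10, 1, ny)
  mats <- list(tissue = tissue_material())
  n <- nrow(m$nodes)
  bot <- which(abs(m$nodes[, 2]) < 1e-9)
  top <- which(abs(m$nodes[, 2] - 10) < 1e-9)
  bc <- list(dofs = c(2L * (1:n) - 1L, 2L * bot, 2L * top),
             values = c(rep(0, n + length(bot)),
                        rep(10 * (stretch - 1), length(top))))
  settings <- settings %||% solver_settings(load_steps = 5, newton_tolerance = 1e-9)
  pre <- foamfea:::precompute_fe(m)
  sol <- foamfea:::ramp_solve(m, mats, function(s) {
    b <- bc
    b$values <- b$values * s
    b
  }, 0, 1, numeric(pre$ndof), NULL, list(), settings, pre, 5)
  list(mesh = m, sol = sol, top = top, bot = bot,
       constants = mats$tissue$constants)
}

# closed-form axial nominal stress of the confined neo-Hookean column
confined_closed_form <- function(stretch, cst) {
  cst$G * (stretch - 1 / stretch) + cst$lambda * log(stretch) / stretch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- memoized reference-suite solve ----------------------------------------

.ref_cache <- new.env(parent = emptyenv())

reference_suite_results <- function() {
  if (!exists("suite_results", .ref_cache)) {
    suite <- generate_scenario_suite()
    assign("suite", suite, .ref_cache)
    assign("suite_results", run_scenario_suite(suite, progress = FALSE),
           .ref_cache)
  }
  get("suite_results", .ref_cache)
}

reference_suite <- function() {
  invisible(reference_suite_results())
  get("suite", .ref_cache)
}
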