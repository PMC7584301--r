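# Quasi-static nonlinear solution: Newton iteration with optional line
# search, incremental load stepping with automatic halving, and a
# safeguarded secant outer loop that scales the driving displacement until
# the mattress-base reaction reaches its target.

#' Solver settings
#'
#' @param load_steps Number of equal displacement increments per ramp.
#' @param newton_tolerance Relative residual norm for convergence.
#' @param max_newton_iterations Iteration cap per increment.
#' @param force_target_tolerance Reaction-force tolerance, N.
#' @param line_search Enable backtracking line search.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(load_steps = 10, newton_tolerance = 1e-6,
                            max_newton_iterations = 60,
                            force_target_tolerance = 0.1,
                            line_search = TRUE) {
  stopifnot(load_steps >= 1, newton_tolerance > 0,
            max_newton_iterations >= 1, force_target_tolerance > 0)
  structure(list(load_steps = as.integer(load_steps),
                 newton_tolerance = newton_tolerance,
                 max_newton_iterations = as.integer(max_newton_iterations),
                 force_target_tolerance = force_target_tolerance,
                 line_search = isTRUE(line_search)),
            class = "solver_settings")
}

resid_norm <- function(r, free) sqrt(sum(r[free]^2))

#' Newton solution of one equilibrium state
#'
#' Solves the discrete equilibrium for fixed boundary values. Convergence is
#' declared when the free-dof residual norm falls below
#' `newton_tolerance * max(1, ||reaction||, ||f_ext||)`.
#'
#' @param mesh A 2-D `fea_mesh`.
#' @param materials Named region-to-material list (`NULL` entries = rigid).
#' @param bc List with `dofs` (integer, interleaved x/y layout) and `values`
#'   (prescribed displacements, mm).
#' @param settings A [solver_settings()].
#' @param u0 Initial guess (full dof vector) or `NULL`.
#' @param contacts List of [contact_spec()].
#' @param contact_state Committed friction state or `NULL`.
#' @param f_ext External nodal force vector or `NULL`.
#' @param precomp Optional precomputed quadrature data.
#' @return List with the converged displacement `u`, full residual
#'   `r` (reactions at constrained dofs), `iterations`, `converged`,
#'   `contact_state` (committed), `contact_info` and a `log` tibble.
#' @export
newton_solve <- function(mesh, materials, bc, settings = solver_settings(),
                         u0 = NULL, contacts = list(), contact_state = NULL,
                         f_ext = NULL, precomp = NULL) {
  if (is.null(precomp)) precomp <- precompute_fe(mesh)
  ndof <- precomp$ndof
  u <- if (is.null(u0)) numeric(ndof) else u0
  stopifnot(length(u) == ndof)
  if (length(contacts) && is.null(contact_state)) {
    # anchor friction at the step-start configuration
    contact_state <- init_contact_state(mesh, contacts, u)
  }
  u[bc$dofs] <- bc$values
  free <- setdiff(seq_len(ndof), bc$dofs)
  refext <- if (is.null(f_ext)) 0 else sqrt(sum(f_ext^2))
  log <- list()
  converged <- FALSE
  last <- NULL
  stall <- 0L
  rnbest <- Inf
  for (it in seq_len(settings$max_newton_iterations + 1L)) {
    last <- assemble(mesh, materials, u, contacts, contact_state, f_ext,
                     precomp, want_tangent = TRUE)
    rn <- resid_norm(last$residual, free)
    reac <- sqrt(sum(last$residual[bc$dofs]^2))
    ref <- max(1, reac, refext)
    log[[it]] <- c(iteration = it - 1L, residual = rn, reference = ref)
    if (rn <= settings$newton_tolerance * ref) {
      converged <- TRUE
      break
    }
    if (it > settings$max_newton_iterations) break
    du <- tryCatch(
      as.vector(Matrix::solve(last$tangent[free, free, drop = FALSE],
                              -last$residual[free])),
      error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) break
    if (settings$line_search) {
      # backtracking: accept the first step that decreases the residual
      # (penalty-contact kinks make stricter sufficient-decrease rules
      # stall); fall back to the best candidate seen
      alpha <- 1
      best <- NULL
      for (ls in 1:8) {
        utry <- u
        utry[free] <- u[free] + alpha * du
        rtry <- tryCatch(
          assemble(mesh, materials, utry, contacts, contact_state, f_ext,
                   precomp, want_tangent = FALSE),
          error = function(e) NULL)
        if (!is.null(rtry)) {
          rtn <- resid_norm(rtry$residual, free)
          if (is.null(best) || rtn < best$rn) best <- list(u = utry, rn = rtn)
          if (rtn < rn) break
        }
        alpha <- alpha / 2
      }
      if (is.null(best)) break
      u <- best$u
      # stagnation/limit-cycle watchdog: abort when the best residual seen
      # so far stops improving, so the ramp can cut the increment
      if (best$rn < 0.995 * rnbest) {
        rnbest <- best$rn
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= 8L) break
      }
    } else {
      u[free] <- u[free] + du
    }
  }
  logdf <- tibble::as_tibble(do.call(rbind, log))
  list(u = u, r = last$residual, iterations = nrow(logdf) - 1L,
       converged = converged,
       contact_state = last$contact_state, contact_info = last$contact_info,
       log = logdf)
}

#' Reaction force on a named surface
#'
#' Sums the residual (internal minus external force) over the nodes of a
#' named set; at constrained nodes this is the support reaction. For 2-D
#' plane-strain solutions the per-unit-depth force is scaled by the
#' mesh's out-of-plane depth and reported in N.
#'
#' @param solution A solved state (an `fea_solution` or the list returned by
#'   [newton_solve()] plus a `mesh` entry).
#' @param surface Name of a node set of the mesh.
#' @param mesh The mesh (required when `solution` lacks one).
#' @return Named numeric `c(x =, y =)` force vector, N.
#' @export
reaction_force <- function(solution, surface, mesh = solution$mesh) {
  if (is.null(mesh)) stop("mesh required", call. = FALSE)
  ids <- mesh$sets[[surface]]
  if (is.null(ids)) stop("unknown surface '", surface, "'", call. = FALSE)
  r <- solution$r
  fx <- sum(r[2L * ids - 1L])
  fy <- sum(r[2L * ids])
  scale <- if (mesh$dim == 2L) mesh$depth * 1e-3 else 1e-3
  c(x = fx * scale, y = fy * scale)
}

# Ramp the prescribed displacement from scale s0 (state u0) to s1 in nsteps
# increments, halving the increment on nonconvergence. bc_at(s) returns the
# bc list at displacement scale s.
ramp_solve <- function(mesh, materials, bc_at, s0, s1, u0, contact_state,
                       contacts, settings, precomp, nsteps) {
  u <- u0
  st <- contact_state
  s <- s0
  step <- (s1 - s0) / nsteps
  minstep <- (s1 - s0) / (nsteps * 64)
  lastsol <- NULL
  uprev <- NULL
  sprev <- NULL
  while (s < s1 - 1e-12 * abs(s1)) {
    stry <- min(s + step, s1)
    # linear extrapolation of the previous increment as predictor
    upred <- if (!is.null(uprev) && s > sprev) {
      u + (u - uprev) * (stry - s) / (s - sprev)
    } else u
    sol <- tryCatch(
      newton_solve(mesh, materials, bc_at(stry), settings, upred, contacts,
                   st, precomp = precomp),
      error = function(e) list(converged = FALSE, error = e))
    if (!isTRUE(sol$converged) && !identical(upred, u)) {
      # retry without the predictor before cutting the step
      sol <- tryCatch(
        newton_solve(mesh, materials, bc_at(stry), settings, u, contacts,
                     st, precomp = precomp),
        error = function(e) list(converged = FALSE, error = e))
    }
    if (!isTRUE(sol$converged)) {
      step <- step / 2
      if (step < minstep) {
        stop("nonconvergence during load ramp near scale ", signif(stry, 6),
             call. = FALSE)
      }
      next
    }
    uprev <- u
    sprev <- s
    s <- stry
    u <- sol$u
    st <- sol$contact_state
    lastsol <- sol
    step <- min(step * 1.5, (s1 - s0) / nsteps)
  }
  lastsol
}

#' Force-targeted oblique loading solve
#'
#' Drives the bone region along a fixed direction (angled from the mattress
#' normal) and scales the displacement magnitude with a safeguarded secant
#' iteration until the reaction-force magnitude on the mattress base equals
#' the target (default 40 N within 0.1 N).
#'
#' @param mesh A 2-D layered `fea_mesh` with `bone_surface` and
#'   `mattress_base` sets.
#' @param materials Named region-to-material list; `bone` may be `NULL`
#'   (rigid driver, the default scenario setup).
#' @param load A [load_case()].
#' @param contacts List of [contact_spec()].
#' @param settings A [solver_settings()].
#' @param extra_bc Optional additional constraints: list with `dofs` and
#'   `values` (held fixed, not scaled with the load).
#' @return An `fea_solution` object; see [solve_case()].
#' @export
force_targeted_solve <- function(mesh, materials, load = load_case(),
                                 contacts = list(),
                                 settings = solver_settings(),
                                 extra_bc = NULL) {
  precomp <- precompute_fe(mesh)
  ang <- load$direction_angle * pi / 180
  dir <- c(sin(ang), -cos(ang)) # caudal-tilted, pressing into the mattress
  bone <- mesh$sets$bone_surface
  base <- mesh$sets$mattress_base
  if (!length(bone)) stop("mesh has no bone_surface set", call. = FALSE)
  bcd <- c(rbind(2L * bone - 1L, 2L * bone), rbind(2L * base - 1L, 2L * base))
  nb <- length(bone)
  bc_at <- function(s) {
    vals <- c(rep(dir, nb) * s * load$max_displacement_guess,
              rep(0, 2L * length(base)))
    if (!is.null(extra_bc)) {
      keep <- !extra_bc$dofs %in% bcd
      return(list(dofs = c(bcd, extra_bc$dofs[keep]),
                  values = c(vals, extra_bc$values[keep])))
    }
    list(dofs = bcd, values = vals)
  }
  fmag <- function(sol) {
    f <- reaction_force(sol, "mattress_base", mesh)
    sqrt(sum(f^2))
  }

  # ramp up, watching the reaction
  nst <- settings$load_steps
  scales <- seq(0, 1, length.out = nst + 1L)[-1]
  hist <- list(list(s = 0, F = 0, u = numeric(precomp$ndof), st = NULL))
  sol <- NULL
  bracket <- NULL
  for (k in seq_along(scales)) {
    prev <- hist[[length(hist)]]
    sol <- ramp_solve(mesh, materials, bc_at, prev$s, scales[k], prev$u,
                      prev$st, contacts, settings, precomp, 1)
    Fk <- fmag(sol)
    hist[[length(hist) + 1L]] <- list(s = scales[k], F = Fk, u = sol$u,
                                      st = sol$contact_state)
    if (Fk >= load$target_reaction_force) {
      bracket <- list(lo = prev, hi = hist[[length(hist)]])
      break
    }
  }
  if (is.null(bracket)) {
    attained <- hist[[length(hist)]]$F
    stop("target-unreachable: reaction reached ", signif(attained, 5),
         " N < target ", load$target_reaction_force,
         " N at max_displacement_guess = ", load$max_displacement_guess,
         " mm", call. = FALSE)
  }

  target <- load$target_reaction_force
  tol <- settings$force_target_tolerance
  lo <- bracket$lo
  hi <- bracket$hi
  best <- if (abs(hi$F - target) < abs(lo$F - target)) hi else lo
  for (iter in 1:25) {
    if (abs(best$F - target) <= tol) break
    # secant on the bracket, safeguarded by bisection
    s <- lo$s + (target - lo$F) * (hi$s - lo$s) / (hi$F - lo$F)
    if (!is.finite(s) || s <= lo$s || s >= hi$s) s <- (lo$s + hi$s) / 2
    # always re-load from the lower bracket state: friction is path-dependent
    # and the loading history must stay monotone
    sol <- ramp_solve(mesh, materials, bc_at, lo$s, s, lo$u, lo$st,
                      contacts, settings, precomp, 1)
    Fk <- fmag(sol)
    pt <- list(s = s, F = Fk, u = sol$u, st = sol$contact_state)
    if (abs(Fk - target) < abs(best$F - target)) best <- pt
    if (Fk < target) lo <- pt else hi <- pt
  }
  if (abs(best$F - target) > tol) {
    stop("force targeting did not reach ", target, " N within ", tol,
         " N (best ", signif(best$F, 6), " N)", call. = FALSE)
  }
  # re-solve at the best scale if the last solve was not it
  if (!identical(sol$u, best$u)) {
    sol <- newton_solve(mesh, materials, bc_at(best$s), settings, best$u,
                        contacts, best$st, precomp = precomp)
  }
  new_fea_solution(mesh, materials, sol, precomp,
                   load = load, scale = best$s,
                   displacement_magnitude = best$s *
                     load$max_displacement_guess)
}

#' Load case for the semi-seated (45 degree) posture
#'
#' A displacement is applied to the bone along a direction tilted caudally
#' from the mattress normal and scaled until the total mattress-base
#' reaction reaches the target force.
#'
#' @param direction_angle Degrees from the mattress normal, caudal positive;
#'   default 45.
#' @param target_reaction_force Target mattress reaction magnitude, N;
#'   default 40.
#' @param max_displacement_guess Upper bound on the driving displacement
#'   magnitude, mm.
#' @return An object of class `load_case`.
#' @export
load_case <- function(direction_angle = 45, target_reaction_force = 40,
                      max_displacement_guess = 25) {
  stopifnot(direction_angle >= 0, direction_angle < 90,
            target_reaction_force > 0, max_displacement_guess > 0)
  structure(list(direction_angle = direction_angle,
                 target_reaction_force = target_reaction_force,
                 max_displacement_guess = max_displacement_guess),
            class = "load_case")
}

new_fea_solution <- function(mesh, materials, sol, precomp = NULL, ...) {
  if (is.null(precomp)) precomp <- precompute_fe(mesh)
  flds <- element_fields(mesh, materials, sol$u, precomp)
  structure(list(mesh = mesh, materials = materials, u = sol$u,
                 r = sol$r, sed = flds$sed, stress = flds$stress,
                 element_volume = flds$volume,
                 converged = sol$converged, iterations = sol$iterations,
                 log = sol$log, contact_state = sol$contact_state,
                 contact_info = sol$contact_info, ...),
            class = "fea_solution")
}

#' @export
print.fea_solution <- function(x, ...) {
  cat("<fea_solution>", if (x$converged) "converged" else "NOT converged",
      sprintf("(%d nodes, %d elements)\n", nrow(x$mesh$nodes),
              nrow(x$mesh$elements)))
  if (!is.null(x$displacement_magnitude)) {
    cat(sprintf("  driving displacement %.3f mm\n", x$displacement_magnitude))
  }
  f <- try(reaction_force(x, "mattress_base"), silent = TRUE)
  if (!inherits(f, "try-error")) {
    cat(sprintf("  mattress-base reaction (%.3f, %.3f) N, |F| = %.3f N\n",
                f[1], f[2], sqrt(sum(f^2))))
  }
  cat(sprintf("  peak tissue SED %.4g kPa\n",
              suppressWarnings(max(x$sed[x$mesh$region == "tissue"]))))
  invisible(x)
}

#' Nodal displacement field of a solution as a matrix
#'
#' @param solution An `fea_solution`.
#' @return An `n_nodes x dim` matrix, mm.
#' @export
displacement_field <- function(solution) {
  matrix(solution$u, ncol = solution$mesh$dim, byrow = TRUE)
}
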