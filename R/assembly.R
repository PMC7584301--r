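# Finite-element assembly for 2-D plane-strain quadrilaterals.
#
# Total-Lagrangian formulation. Near-incompressibility is handled by
# selective reduced integration: the G-terms of the neo-Hookean energy are
# integrated at 2x2 Gauss points, the volumetric lambda/2 (ln J)^2 term at
# the element centroid only (mean-dilatation family). Residual and tangent
# are exact derivatives of the so-integrated element energy, so the tangent
# is consistent and symmetric.

GAUSS_2x2 <- {
  g <- 1 / sqrt(3)
  list(list(xi = -g, eta = -g, w = 1), list(xi = g, eta = -g, w = 1),
       list(xi = g, eta = g, w = 1), list(xi = -g, eta = g, w = 1))
}
GAUSS_CENTER <- list(xi = 0, eta = 0, w = 4)

#' Precompute element quadrature data for a 2-D mesh
#'
#' Reference shape-function gradients, Jacobian weights and scatter indices
#' reused across assemblies. Called automatically by the solver.
#'
#' @param mesh A 2-D `fea_mesh`.
#' @return An opaque list consumed by [assemble()].
#' @keywords internal
precompute_fe <- function(mesh) {
  stopifnot(mesh$dim == 2L)
  e <- mesh$elements
  ne <- nrow(e)
  X1 <- matrix(mesh$nodes[e, 1], ncol = 4)
  X2 <- matrix(mesh$nodes[e, 2], ncol = 4)
  gps <- c(GAUSS_2x2, list(GAUSS_CENTER))
  gp <- lapply(gps, function(p) {
    dN <- quad_shape_grad(p$xi, p$eta) # 4 x 2 in reference (xi) coords
    J11 <- X1 %*% dN[, 1]; J12 <- X2 %*% dN[, 1]
    J21 <- X1 %*% dN[, 2]; J22 <- X2 %*% dN[, 2]
    detJ <- as.vector(J11 * J22 - J12 * J21)
    if (any(detJ <= 0)) {
      stop("mesh has non-positive Jacobian at a quadrature point (element ",
           which(detJ <= 0)[1], ")", call. = FALSE)
    }
    # dN_a/dx_i = sum_j dN_a/dxi_j [inv(Ju)]_{ji} with Ju_{ij} = dx_i/dxi_j;
    # in the component layout above Ju = [J11 J21; J12 J22], so
    # inv(Ju) = [J22 -J21; -J12 J11] / detJ
    dN1 <- matrix(0, ne, 4); dN2 <- matrix(0, ne, 4)
    for (a in 1:4) {
      dN1[, a] <- (dN[a, 1] * J22 - dN[a, 2] * J12) / detJ
      dN2[, a] <- (-dN[a, 1] * J21 + dN[a, 2] * J11) / detJ
    }
    list(dN1 = dN1, dN2 = dN2, wdet = p$w * detJ)
  })
  # local dof l = 2*(a-1)+i maps to global dof 2*(node-1)+i
  edof <- matrix(0L, ne, 8)
  for (a in 1:4) {
    edof[, 2 * a - 1L] <- 2L * e[, a] - 1L
    edof[, 2 * a] <- 2L * e[, a]
  }
  ii <- edof[, rep(1:8, times = 8), drop = FALSE]
  jj <- edof[, rep(1:8, each = 8), drop = FALSE]
  ndof <- 2L * nrow(mesh$nodes)
  # cache the bulk sparsity pattern: per-assembly we only replace @x
  iv <- as.vector(ii)
  jv <- as.vector(jj)
  code <- (jv - 1) * as.double(ndof) + iv
  K0 <- Matrix::sparseMatrix(i = iv, j = jv, x = 0, dims = c(ndof, ndof))
  xmap <- match(code, sort(unique(code)))
  list(gp = gp, edof = edof, ii = ii, jj = jj, ne = ne, ndof = ndof,
       K0 = K0, xmap = xmap, nx = length(K0@x))
}

# Deformation gradient components at one quadrature point for a subset of
# elements. ux, uy are ne x 4 matrices of nodal displacements.
gp_defgrad <- function(g, idx, ux, uy) {
  dN1 <- g$dN1[idx, , drop = FALSE]
  dN2 <- g$dN2[idx, , drop = FALSE]
  list(F11 = 1 + rowSums(dN1 * ux), F12 = rowSums(dN2 * ux),
       F21 = rowSums(dN1 * uy), F22 = 1 + rowSums(dN2 * uy),
       dN1 = dN1, dN2 = dN2, wdet = g$wdet[idx])
}

add_point_residual <- function(fe, d, P) {
  # fe: nidx x 8 accumulator; P: list of stress component vectors
  for (a in 1:4) {
    fe[, 2 * a - 1L] <- fe[, 2 * a - 1L] +
      d$wdet * (P$P11 * d$dN1[, a] + P$P12 * d$dN2[, a])
    fe[, 2 * a] <- fe[, 2 * a] +
      d$wdet * (P$P21 * d$dN1[, a] + P$P22 * d$dN2[, a])
  }
  fe
}

add_point_tangent <- function(Ke, d, A) {
  # Ke: nidx x 64 accumulator, column (lcol-1)*8 + lrow. The inner products
  # over the reference index I are shared across the row node a.
  dN1 <- d$dN1; dN2 <- d$dN2
  w <- d$wdet
  for (i in 1:2) for (j in 1:2) {
    Ai1j1 <- A[[i, 1, j, 1]]; Ai1j2 <- A[[i, 1, j, 2]]
    Ai2j1 <- A[[i, 2, j, 1]]; Ai2j2 <- A[[i, 2, j, 2]]
    for (b in 1:4) {
      t1 <- w * (Ai1j1 * dN1[, b] + Ai1j2 * dN2[, b])
      t2 <- w * (Ai2j1 * dN1[, b] + Ai2j2 * dN2[, b])
      base <- (2L * (b - 1L) + j - 1L) * 8L + i
      for (a in 1:4) {
        k <- base + 2L * (a - 1L)
        Ke[, k] <- Ke[, k] + dN1[, a] * t1 + dN2[, a] * t2
      }
    }
  }
  Ke
}

#' Assemble the residual and consistent tangent of the discrete problem
#'
#' Computes the out-of-balance force `residual = f_internal + f_contact -
#' f_external` and (optionally) its consistent linearization, including
#' penalty-contact contributions. Regions whose material is `NULL` (e.g. a
#' rigid, displacement-driven bone) are skipped.
#'
#' @param mesh A 2-D `fea_mesh`.
#' @param materials Named list mapping region labels to [materials] (or
#'   `NULL` for rigid regions).
#' @param u Nodal displacement vector (length `2 * n_nodes`, interleaved
#'   x/y) or an `n_nodes x 2` matrix.
#' @param contacts List of [contact_spec()] pairs.
#' @param contact_state Internal friction state as returned by a previous
#'   assembly/solve; `NULL` to initialize.
#' @param f_ext External nodal force vector (same layout as `u`), or `NULL`.
#' @param precomp Result of `precompute_fe(mesh)`; recomputed when `NULL`.
#' @param want_tangent Assemble the sparse tangent matrix?
#' @return List with `residual`, `tangent` (a `dgCMatrix` or `NULL`),
#'   `contact_state`, and `contact_info` (per-slave-node diagnostics).
#' @export
assemble <- function(mesh, materials, u, contacts = list(),
                     contact_state = NULL, f_ext = NULL, precomp = NULL,
                     want_tangent = TRUE) {
  if (is.null(precomp)) precomp <- precompute_fe(mesh)
  if (is.matrix(u)) u <- as.vector(t(u))
  stopifnot(length(u) == precomp$ndof)
  e <- mesh$elements
  ne <- precomp$ne
  ux <- matrix(u[2L * e - 1L], ncol = 4)
  uy <- matrix(u[2L * e], ncol = 4)

  fe <- matrix(0, ne, 8)
  Ke <- if (want_tangent) matrix(0, ne, 64) else NULL

  for (reg in unique(mesh$region)) {
    mat <- materials[[reg]]
    if (is.null(mat)) next # rigid / displacement-driven region
    idx <- which(mesh$region == reg)
    cst <- mat$constants
    fer <- matrix(0, length(idx), 8)
    Ker <- if (want_tangent) matrix(0, length(idx), 64) else NULL
    uxr <- ux[idx, , drop = FALSE]
    uyr <- uy[idx, , drop = FALSE]
    if (mat$family == "neo_hookean") {
      for (g in precomp$gp[1:4]) {
        d <- gp_defgrad(g, idx, uxr, uyr)
        k <- nh_kinematics(d$F11, d$F12, d$F21, d$F22)
        if (any(k$J <= 0)) {
          stop("state-invalid: inverted element during assembly (element ",
               idx[which(k$J <= 0)[1]], ")", call. = FALSE)
        }
        fer <- add_point_residual(fer, d, nh_pk1_G(k, d$F11, d$F12, d$F21,
                                                   d$F22, cst$G))
        if (want_tangent) Ker <- add_point_tangent(Ker, d, nh_tangent_G(k, cst$G))
      }
      d0 <- gp_defgrad(precomp$gp[[5]], idx, uxr, uyr)
      k0 <- nh_kinematics(d0$F11, d0$F12, d0$F21, d0$F22)
      if (any(k0$J <= 0)) {
        stop("state-invalid: inverted element during assembly (element ",
             idx[which(k0$J <= 0)[1]], ")", call. = FALSE)
      }
      fer <- add_point_residual(fer, d0, nh_pk1_vol(k0, cst$lambda))
      if (want_tangent) {
        Ker <- add_point_tangent(Ker, d0, nh_tangent_vol(k0, cst$lambda))
      }
    } else {
      for (g in precomp$gp[1:4]) {
        d <- gp_defgrad(g, idx, uxr, uyr)
        fer <- add_point_residual(
          fer, d, lin_stress(d$F11 - 1, d$F12, d$F21, d$F22 - 1, cst$G,
                             cst$lambda))
        if (want_tangent) {
          Ker <- add_point_tangent(Ker, d,
                                   lin_tangent(length(idx), cst$G, cst$lambda))
        }
      }
    }
    fe[idx, ] <- fe[idx, ] + fer
    if (want_tangent) Ke[idx, ] <- Ke[idx, ] + Ker
  }

  r <- numeric(precomp$ndof)
  rs <- rowsum(as.vector(fe), as.vector(precomp$edof))
  r[as.integer(rownames(rs))] <- rs

  # contact
  new_state <- contact_state
  contact_info <- NULL
  ctrip <- NULL
  if (length(contacts)) {
    if (is.null(new_state)) new_state <- init_contact_state(mesh, contacts)
    cres <- contact_assemble_all(mesh, materials, u, contacts, new_state,
                                 want_tangent)
    r <- r + cres$r # contact internal force (spring resists penetration)
    new_state <- cres$state
    contact_info <- cres$info
    ctrip <- cres$triplets
  }

  if (!is.null(f_ext)) {
    if (is.matrix(f_ext)) f_ext <- as.vector(t(f_ext))
    r <- r - f_ext
  }

  K <- NULL
  if (want_tangent) {
    acc <- rowsum(as.vector(Ke), precomp$xmap)
    K <- precomp$K0
    K@x <- acc[, 1]
    if (!is.null(ctrip) && length(ctrip$i)) {
      K <- K + Matrix::sparseMatrix(i = ctrip$i, j = ctrip$j, x = ctrip$x,
                                    dims = c(precomp$ndof, precomp$ndof))
    }
  }
  list(residual = r, tangent = K, contact_state = new_state,
       contact_info = contact_info)
}

# ---- per-element field evaluation ------------------------------------------

# Per-element strain energy density (volume average, kPa) and Cauchy stress
# components (s11, s22, s12, s33; volume-averaged over Gauss points).
element_fields <- function(mesh, materials, u, precomp = NULL) {
  if (is.null(precomp)) precomp <- precompute_fe(mesh)
  if (is.matrix(u)) u <- as.vector(t(u))
  e <- mesh$elements
  ne <- precomp$ne
  ux <- matrix(u[2L * e - 1L], ncol = 4)
  uy <- matrix(u[2L * e], ncol = 4)
  W <- numeric(ne)
  S <- matrix(0, ne, 4, dimnames = list(NULL, c("s11", "s22", "s12", "s33")))
  V <- numeric(ne)
  for (reg in unique(mesh$region)) {
    mat <- materials[[reg]]
    idx <- which(mesh$region == reg)
    if (is.null(mat)) { V[idx] <- 1; next }
    cst <- mat$constants
    uxr <- ux[idx, , drop = FALSE]
    uyr <- uy[idx, , drop = FALSE]
    Wr <- numeric(length(idx))
    Sr <- matrix(0, length(idx), 4)
    Vr <- numeric(length(idx))
    if (mat$family == "neo_hookean") {
      d0 <- gp_defgrad(precomp$gp[[5]], idx, uxr, uyr)
      k0 <- nh_kinematics(d0$F11, d0$F12, d0$F21, d0$F22)
      lnJ0 <- log(k0$J)
      for (g in precomp$gp[1:4]) {
        d <- gp_defgrad(g, idx, uxr, uyr)
        k <- nh_kinematics(d$F11, d$F12, d$F21, d$F22)
        I1 <- d$F11^2 + d$F12^2 + d$F21^2 + d$F22^2 + 1
        Wr <- Wr + d$wdet * (cst$G / 2 * (I1 - 3) - cst$G * log(k$J))
        # Cauchy: G(B - I)/J at the point + volumetric part from the centroid
        B11 <- d$F11^2 + d$F12^2
        B22 <- d$F21^2 + d$F22^2
        B12 <- d$F11 * d$F21 + d$F12 * d$F22
        pvol <- cst$lambda * lnJ0 / k0$J
        Sr[, 1] <- Sr[, 1] + d$wdet * (cst$G * (B11 - 1) / k$J + pvol)
        Sr[, 2] <- Sr[, 2] + d$wdet * (cst$G * (B22 - 1) / k$J + pvol)
        Sr[, 3] <- Sr[, 3] + d$wdet * (cst$G * B12 / k$J)
        Sr[, 4] <- Sr[, 4] + d$wdet * pvol # B33 = 1 in plane strain
        Vr <- Vr + d$wdet
      }
      Wr <- Wr + d0$wdet * cst$lambda / 2 * lnJ0^2
    } else {
      for (g in precomp$gp[1:4]) {
        d <- gp_defgrad(g, idx, uxr, uyr)
        e11 <- d$F11 - 1; e22 <- d$F22 - 1
        e12 <- 0.5 * (d$F12 + d$F21)
        tr <- e11 + e22
        Wr <- Wr + d$wdet * (cst$lambda / 2 * tr^2 +
                               cst$G * (e11^2 + e22^2 + 2 * e12^2))
        Sr[, 1] <- Sr[, 1] + d$wdet * (cst$lambda * tr + 2 * cst$G * e11)
        Sr[, 2] <- Sr[, 2] + d$wdet * (cst$lambda * tr + 2 * cst$G * e22)
        Sr[, 3] <- Sr[, 3] + d$wdet * (2 * cst$G * e12)
        Sr[, 4] <- Sr[, 4] + d$wdet * (cst$lambda * tr)
        Vr <- Vr + d$wdet
      }
    }
    W[idx] <- Wr / pmax(Vr, .Machine$double.eps)
    S[idx, ] <- Sr / pmax(Vr, .Machine$double.eps)
    V[idx] <- Vr
  }
  list(sed = W, stress = S, volume = V)
}
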