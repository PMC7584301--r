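#' Material models
#'
#' Two constitutive families are supported:
#'
#' * `neo_hookean`: compressible neo-Hookean hyperelasticity with energy
#'   \deqn{W = (G/2)(I_1 - 3) - G \ln J + (\lambda/2)(\ln J)^2,}
#'   the classical form whose small-strain limit reproduces the linear
#'   isotropic constants. Near-incompressibility (e.g. soft tissue at
#'   \eqn{\nu = 0.495}) is handled at the element level by selective reduced
#'   integration of the \eqn{\lambda}-term.
#' * `linear_elastic`: geometrically linear small-strain isotropic
#'   elasticity, \eqn{\sigma = \lambda \mathrm{tr}(\varepsilon) I +
#'   2G\varepsilon} with \eqn{\varepsilon = \mathrm{sym}(\nabla u)}.
#'
#' @param constants An [elastic_constants()] object.
#' @param solid_fraction Solid volume fraction of a foam, in (0, 1]. Carried
#'   as metadata for porous dressing foams (default 1 = solid).
#' @param name Optional material label.
#' @return An object of class `fea_material`.
#' @examples
#' tissue <- material_neo_hookean(elastic_constants(G = 19.254, K = 1919.022))
#' bone <- material_linear_elastic(elastic_constants(E = 3.4e6, nu = 0.36))
#' @name materials
NULL

new_material <- function(family, constants, solid_fraction = 1,
                         name = family, thickness = NA_real_) {
  stopifnot(inherits(constants, "elastic_constants"))
  if (!is.numeric(solid_fraction) || length(solid_fraction) != 1L ||
      solid_fraction <= 0 || solid_fraction > 1) {
    stop("solid_fraction must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(family = family, constants = constants,
         solid_fraction = solid_fraction, name = name,
         thickness = thickness),
    class = "fea_material"
  )
}

#' @rdname materials
#' @export
material_neo_hookean <- function(constants, solid_fraction = 1,
                                 name = "neo_hookean") {
  new_material("neo_hookean", constants, solid_fraction, name)
}

#' @rdname materials
#' @export
material_linear_elastic <- function(constants, name = "linear_elastic") {
  new_material("linear_elastic", constants, 1, name)
}

#' @export
print.fea_material <- function(x, ...) {
  cat(sprintf("<fea_material> %s (%s): %s", x$name, x$family,
              format(x$constants)))
  if (x$solid_fraction < 1) {
    cat(sprintf(", solid fraction %.3g", x$solid_fraction))
  }
  if (is.finite(x$thickness)) cat(sprintf(", thickness %.3g mm", x$thickness))
  cat("\n")
  invisible(x)
}

#' Construct a dressing foam material from its effective indentation modulus
#'
#' Builds a neo-Hookean material whose small-strain Young's modulus equals the
#' effective modulus identified from flat-punch indentation. Silicone foam
#' dressings are modeled as compressible foams with a low Poisson ratio
#' (default 0.1); the solid volume fraction of the foam (default 2%) is
#' recorded as metadata.
#'
#' @param effective_modulus Effective Young's modulus, kPa (> 0).
#' @param thickness Foam thickness, mm (> 0).
#' @param solid_fraction Solid volume fraction in (0, 1]; default 0.02.
#' @param poisson Foam Poisson ratio; default 0.1.
#' @param name Dressing label.
#' @return A `fea_material` of family `neo_hookean` with the dressing
#'   thickness and solid fraction attached.
#' @examples
#' dressing_material(19.0, 5.50, name = "TSF")
#' @export
dressing_material <- function(effective_modulus, thickness,
                              solid_fraction = 0.02, poisson = 0.1,
                              name = "dressing") {
  if (!is.numeric(effective_modulus) || effective_modulus <= 0) {
    stop("effective_modulus must be > 0", call. = FALSE)
  }
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("thickness must be > 0", call. = FALSE)
  }
  cst <- elastic_constants(E = effective_modulus, nu = poisson)
  new_material("neo_hookean", cst, solid_fraction, name, thickness)
}

# ---- deformation-state helpers ----------------------------------------------

#' Promote a deformation gradient to 3x3
#'
#' 2x2 plane-strain gradients are embedded with F33 = 1; 3x3 inputs are
#' returned unchanged. Errors if det(F) <= 0.
#' @param F A 2x2 or 3x3 deformation gradient.
#' @return A 3x3 matrix.
#' @keywords internal
promote_F <- function(F) {
  F <- as.matrix(F)
  if (all(dim(F) == c(2L, 2L))) {
    F3 <- diag(3)
    F3[1:2, 1:2] <- F
    F <- F3
  }
  stopifnot(all(dim(F) == c(3L, 3L)))
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("inverted deformation state: det(F) = ", signif(J, 6), " <= 0",
         call. = FALSE)
  }
  F
}

#' Strain energy density of a material at a deformation gradient
#'
#' Energy per unit reference volume, kPa. Zero at the identity; for the
#' neo-Hookean family it depends on F only through the invariants
#' \eqn{I_1 = \mathrm{tr}(F^T F)} and \eqn{J = \det F} (frame invariance).
#'
#' @param F Deformation gradient, 2x2 (plane strain, promoted with F33 = 1)
#'   or 3x3, with det(F) > 0.
#' @param material A `fea_material`.
#' @return Scalar energy density, kPa.
#' @examples
#' tissue <- material_neo_hookean(elastic_constants(G = 19.254, K = 1919.022))
#' strain_energy_density(diag(2), tissue) # 0 at rest
#' @export
strain_energy_density <- function(F, material) {
  stopifnot(inherits(material, "fea_material"))
  F <- promote_F(F)
  cst <- material$constants
  if (material$family == "neo_hookean") {
    J <- det(F)
    I1 <- sum(F * F)
    cst$G / 2 * (I1 - 3) - cst$G * log(J) + cst$lambda / 2 * log(J)^2
  } else {
    eps <- 0.5 * (F + t(F)) - diag(3)
    cst$lambda / 2 * sum(diag(eps))^2 + cst$G * sum(eps * eps)
  }
}

#' Cauchy stress of a material at a deformation gradient
#'
#' For the neo-Hookean family \eqn{\sigma = (G(B - I) + \lambda \ln J\, I)/J}
#' with \eqn{B = F F^T}; for the linear family the small-strain Hooke law.
#' The returned tensor is symmetric and zero at the identity.
#'
#' @inheritParams strain_energy_density
#' @return A 3x3 symmetric stress tensor, kPa.
#' @export
cauchy_stress <- function(F, material) {
  stopifnot(inherits(material, "fea_material"))
  F <- promote_F(F)
  cst <- material$constants
  if (material$family == "neo_hookean") {
    J <- det(F)
    B <- F %*% t(F)
    (cst$G * (B - diag(3)) + cst$lambda * log(J) * diag(3)) / J
  } else {
    eps <- 0.5 * (F + t(F)) - diag(3)
    cst$lambda * sum(diag(eps)) * diag(3) + 2 * cst$G * eps
  }
}

#' First Piola-Kirchhoff stress (derivative of the energy w.r.t. F)
#'
#' @inheritParams strain_energy_density
#' @return A 3x3 tensor, kPa.
#' @keywords internal
pk1_stress <- function(F, material) {
  F <- promote_F(F)
  cst <- material$constants
  if (material$family == "neo_hookean") {
    J <- det(F)
    FinvT <- t(solve(F))
    cst$G * (F - FinvT) + cst$lambda * log(J) * FinvT
  } else {
    # sigma(eps(F)); work-conjugacy in the geometrically linear sense
    cauchy_stress(F, material)
  }
}

#' Material tangent dP/dF at a deformation gradient
#'
#' Fourth-order tangent \eqn{A_{iIjJ} = \partial P_{iI}/\partial F_{jJ}}
#' returned as a 3x3x3x3 array (indices i, I, j, J). Possesses major symmetry
#' \eqn{A_{iIjJ} = A_{jJiI}} since it derives from an energy.
#'
#' @inheritParams strain_energy_density
#' @return A numeric array of dim c(3, 3, 3, 3), kPa.
#' @export
material_tangent <- function(F, material) {
  stopifnot(inherits(material, "fea_material"))
  F <- promote_F(F)
  cst <- material$constants
  A <- array(0, c(3, 3, 3, 3))
  d <- diag(3)
  if (material$family == "neo_hookean") {
    J <- det(F)
    lnJ <- log(J)
    FiT <- t(solve(F)) # FiT[i, I] = F^{-T}_{iI}
    for (i in 1:3) for (I in 1:3) for (j in 1:3) for (J_ in 1:3) {
      A[i, I, j, J_] <- cst$G * d[i, j] * d[I, J_] +
        cst$lambda * FiT[i, I] * FiT[j, J_] +
        (cst$G - cst$lambda * lnJ) * FiT[i, J_] * FiT[j, I]
    }
  } else {
    for (i in 1:3) for (I in 1:3) for (j in 1:3) for (J_ in 1:3) {
      A[i, I, j, J_] <- cst$lambda * d[i, I] * d[j, J_] +
        cst$G * (d[i, j] * d[I, J_] + d[i, J_] * d[j, I])
    }
  }
  A
}

# ---- vectorized 2-D plane-strain kernels (used by the assembler) ------------

# Components of the in-plane deformation gradient are passed as equal-length
# vectors (one entry per element/quadrature point). Plane strain: F33 = 1,
# J = F11*F22 - F12*F21, I1 = F11^2 + F12^2 + F21^2 + F22^2 + 1.

nh_kinematics <- function(F11, F12, F21, F22) {
  J <- F11 * F22 - F12 * F21
  # F^{-T} components: F^{-T}[i,I] = (F^{-1})[I,i]
  list(J = J,
       iT11 = F22 / J, iT12 = -F21 / J,
       iT21 = -F12 / J, iT22 = F11 / J)
}

# PK1 of the G-part of the neo-Hookean energy: G (F - F^{-T})
nh_pk1_G <- function(k, F11, F12, F21, F22, G) {
  list(P11 = G * (F11 - k$iT11), P12 = G * (F12 - k$iT12),
       P21 = G * (F21 - k$iT21), P22 = G * (F22 - k$iT22))
}

# PK1 of the volumetric lambda-part: lambda ln J F^{-T}
nh_pk1_vol <- function(k, lambda) {
  s <- lambda * log(k$J)
  list(P11 = s * k$iT11, P12 = s * k$iT12,
       P21 = s * k$iT21, P22 = s * k$iT22)
}

# In-plane tangent components A[i,I,j,J] of the G-part, as a function
# returning component vectors: A = G d_ij d_IJ + G FiT[i,J] FiT[j,I]
nh_tangent_G <- function(k, G) {
  iT <- list(list(k$iT11, k$iT12), list(k$iT21, k$iT22))
  A <- vector("list", 16)
  dim(A) <- c(2, 2, 2, 2)
  d <- diag(2)
  for (i in 1:2) for (I in 1:2) for (j in 1:2) for (J_ in 1:2) {
    A[[i, I, j, J_]] <- G * d[i, j] * d[I, J_] +
      G * iT[[i]][[J_]] * iT[[j]][[I]]
  }
  A
}

# Volumetric tangent: lambda FiT_iI FiT_jJ - lambda lnJ FiT_iJ FiT_jI
nh_tangent_vol <- function(k, lambda) {
  lnJ <- log(k$J)
  iT <- list(list(k$iT11, k$iT12), list(k$iT21, k$iT22))
  A <- vector("list", 16)
  dim(A) <- c(2, 2, 2, 2)
  for (i in 1:2) for (I in 1:2) for (j in 1:2) for (J_ in 1:2) {
    A[[i, I, j, J_]] <- lambda * iT[[i]][[I]] * iT[[j]][[J_]] -
      lambda * lnJ * iT[[i]][[J_]] * iT[[j]][[I]]
  }
  A
}

# Linear-elastic small-strain stress from in-plane displacement gradient H
lin_stress <- function(H11, H12, H21, H22, G, lambda) {
  tr <- H11 + H22 # plane strain: eps33 = 0
  list(P11 = lambda * tr + 2 * G * H11,
       P12 = G * (H12 + H21),
       P21 = G * (H12 + H21),
       P22 = lambda * tr + 2 * G * H22)
}

# Constant linear-elastic in-plane tangent (same index convention as above)
lin_tangent <- function(n, G, lambda) {
  A <- vector("list", 16)
  dim(A) <- c(2, 2, 2, 2)
  d <- diag(2)
  one <- rep(1, n)
  for (i in 1:2) for (I in 1:2) for (j in 1:2) for (J_ in 1:2) {
    A[[i, I, j, J_]] <- (lambda * d[i, I] * d[j, J_] +
      G * (d[i, j] * d[I, J_] + d[i, J_] * d[j, I])) * one
  }
  A
}
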