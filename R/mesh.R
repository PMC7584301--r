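#' Parametric layered domain specification
#'
#' Describes the sagittal section (default) of a layered support scenario:
#' a foam mattress, an optional foam dressing, and a soft-tissue block with a
#' rounded bony prominence embedded in it, tip facing the dressing. Stands in
#' parametrically for a subject-specific sacral geometry; the stress-raising
#' "tight radius" of the bone is controlled by `prominence_tip_radius`.
#'
#' Coordinates: x runs caudally along the mattress surface, y is normal to
#' the mattress, origin at the left corner of the mattress base. All lengths
#' in mm.
#'
#' @param tissue_width Width of the soft-tissue block, mm.
#' @param tissue_height Height (skin-to-deep) of the soft-tissue block, mm.
#' @param tissue_depth Out-of-plane depth of the tissue block, mm; meshed
#'   in 3-D mode.
#' @param effective_depth Lateral extent over which the sacral load is
#'   transferred, mm (default 80, about the width of the sacrum). In 2-D
#'   plane strain, per-unit-depth reactions are multiplied by this depth to
#'   report forces in N; using the full block depth would spread the load
#'   over tissue that carries none of it in reality.
#' @param dressing_thickness Dressing foam thickness, mm; 0 means no dressing
#'   (the control case).
#' @param dressing_extent In-plane footprint width of the dressing, mm;
#'   must not exceed `tissue_width`.
#' @param mattress_thickness Mattress thickness, mm.
#' @param prominence_tip_radius Tip radius of the embedded bony prominence,
#'   mm; 0 means no prominence.
#' @param prominence_depth Soft-tissue cover between the prominence tip and
#'   the skin (tissue bottom surface), mm.
#' @param prominence_height Height of the bone body above the tip circle's
#'   centre, mm. The prominence is a rounded capsule fully embedded in the
#'   tissue (tissue continues above it and rides along with the driven
#'   bone), mirroring a sacrum surrounded by soft tissue.
#' @param dimensionality `"2D"` (plane strain, default) or `"3D"` (coarse
#'   extruded hexahedra).
#' @return An object of class `domain_spec`.
#' @examples
#' domain_spec() # the packaged reference geometry with a TSF-thickness dressing
#' domain_spec(dressing_thickness = 0) # the no-dressing control
#' @export
domain_spec <- function(tissue_width = 200, tissue_height = 75,
                        tissue_depth = 250, effective_depth = 80,
                        dressing_thickness = 5.5, dressing_extent = 150,
                        mattress_thickness = 75,
                        prominence_tip_radius = 8, prominence_depth = 15,
                        prominence_height = 35,
                        dimensionality = c("2D", "3D")) {
  dimensionality <- match.arg(dimensionality)
  spec <- list(tissue_width = tissue_width, tissue_height = tissue_height,
               tissue_depth = tissue_depth,
               effective_depth = effective_depth,
               dressing_thickness = dressing_thickness,
               dressing_extent = dressing_extent,
               mattress_thickness = mattress_thickness,
               prominence_tip_radius = prominence_tip_radius,
               prominence_depth = prominence_depth,
               prominence_height = prominence_height,
               dimensionality = dimensionality)
  validate_domain_spec(spec)
  structure(spec, class = "domain_spec")
}

validate_domain_spec <- function(spec) {
  pos <- c("tissue_width", "tissue_height", "tissue_depth",
           "effective_depth", "mattress_thickness")
  for (nm in pos) {
    if (!is.numeric(spec[[nm]]) || spec[[nm]] <= 0) {
      stop("domain_spec: ", nm, " must be > 0", call. = FALSE)
    }
  }
  nonneg <- c("dressing_thickness", "dressing_extent",
              "prominence_tip_radius", "prominence_depth",
              "prominence_height")
  for (nm in nonneg) {
    if (!is.numeric(spec[[nm]]) || spec[[nm]] < 0) {
      stop("domain_spec: ", nm, " must be >= 0", call. = FALSE)
    }
  }
  if (spec$dressing_thickness > 0 && spec$dressing_extent <= 0) {
    stop("domain_spec: a dressing needs dressing_extent > 0", call. = FALSE)
  }
  if (spec$dressing_extent > spec$tissue_width) {
    stop("domain_spec: dressing_extent must not exceed tissue_width",
         call. = FALSE)
  }
  r <- spec$prominence_tip_radius
  if (r > 0) {
    extent <- spec$prominence_depth + r + spec$prominence_height
    if (extent > spec$tissue_height) {
      stop("geometry error: prominence does not fit inside the tissue block ",
           "(prominence_depth + tip_radius + prominence_height exceeds ",
           "tissue_height)", call. = FALSE)
    }
    if (2 * r > spec$tissue_width) {
      stop("geometry error: prominence wider than the tissue block",
           call. = FALSE)
    }
  }
  invisible(spec)
}

#' @export
print.domain_spec <- function(x, ...) {
  cat("<domain_spec> (", x$dimensionality, ")\n", sep = "")
  cat(sprintf("  tissue  %g x %g mm (depth %g mm)\n", x$tissue_width,
              x$tissue_height, x$tissue_depth))
  if (x$dressing_thickness > 0) {
    cat(sprintf("  dressing %g mm thick, footprint %g mm\n",
                x$dressing_thickness, x$dressing_extent))
  } else cat("  no dressing (control)\n")
  cat(sprintf("  mattress %g mm thick\n", x$mattress_thickness))
  if (x$prominence_tip_radius > 0) {
    cat(sprintf("  prominence tip radius %g mm, %g mm below skin\n",
                x$prominence_tip_radius, x$prominence_depth))
  }
  invisible(x)
}

# ---- mesh container ---------------------------------------------------------

#' Construct and validate a finite-element mesh
#'
#' Low-level constructor; most users build meshes with
#' [build_layered_domain()] or [structured_grid()].
#'
#' @param nodes Numeric matrix of node coordinates (n x 2 or n x 3), mm.
#' @param elements Integer matrix of element connectivity (4-node
#'   quadrilaterals in 2-D, 8-node hexahedra in 3-D), counter-clockwise.
#' @param region Character vector of per-element region labels.
#' @param sets Named list of integer node-index vectors (boundary surfaces).
#' @param depth Out-of-plane depth for 2-D meshes, mm.
#' @param spec Optional `domain_spec` provenance.
#' @return An object of class `fea_mesh`.
#' @export
fea_mesh <- function(nodes, elements, region, sets = list(), depth = 1,
                     spec = NULL) {
  nodes <- as.matrix(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  dim_ <- ncol(nodes)
  stopifnot(dim_ %in% c(2L, 3L))
  npe <- if (dim_ == 2L) 4L else 8L
  if (ncol(elements) != npe) {
    stop("fea_mesh: expected ", npe, "-node elements in ", dim_, "-D",
         call. = FALSE)
  }
  if (length(region) != nrow(elements)) {
    stop("fea_mesh: region labels must partition the elements", call. = FALSE)
  }
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("fea_mesh: connectivity index out of range", call. = FALSE)
  }
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    if (length(ids) && (any(ids < 1L) || any(ids > nrow(nodes)))) {
      stop("fea_mesh: node set '", nm, "' references missing nodes",
           call. = FALSE)
    }
  }
  structure(list(nodes = nodes, elements = elements,
                 region = as.character(region), sets = sets,
                 dim = dim_, depth = depth, spec = spec),
            class = "fea_mesh")
}

#' @export
print.fea_mesh <- function(x, ...) {
  cat(sprintf("<fea_mesh> %d-D: %d nodes, %d elements\n", x$dim,
              nrow(x$nodes), nrow(x$elements)))
  tb <- table(x$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  if (length(x$sets)) {
    cat("  sets:", paste(names(x$sets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Structured rectangular grid mesh
#'
#' An nx-by-ny grid of bilinear quadrilaterals on `[x0, x0+width] x
#' [y0, y0+height]`, giving exactly `nx * ny` elements and
#' `(nx + 1) * (ny + 1)` nodes.
#'
#' @param width,height Rectangle dimensions, mm.
#' @param nx,ny Element counts per direction.
#' @param x0,y0 Lower-left corner.
#' @param region Region label applied to every element.
#' @return A `fea_mesh`.
#' @export
structured_grid <- function(width, height, nx, ny, x0 = 0, y0 = 0,
                            region = "tissue") {
  stopifnot(nx >= 1, ny >= 1, width > 0, height > 0)
  xs <- seq(x0, x0 + width, length.out = nx + 1)
  ys <- seq(y0, y0 + height, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  elements <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  fea_mesh(nodes, elements, rep(region, nx * ny))
}

# internal: structured grid pieces without the fea_mesh wrapper
grid_piece <- function(xs, ys, region) {
  nx <- length(xs) - 1L
  ny <- length(ys) - 1L
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  elements <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  list(nodes = nodes, elements = elements, region = rep(region, nx * ny),
       nx = nx, ny = ny)
}

#' Graded mesh control for the layered domain
#'
#' Tensor-product grading that concentrates elements around the bony
#' prominence, where the analysed SED band lives: fine in-plane spacing
#' within `focus_halfwidth` of the prominence axis and fine tissue rows up
#' to `fine_height` above the skin, coarse elsewhere. The mattress gets its
#' own uniform (coarser) grid; the dressing shares the in-plane grid of the
#' tissue so the bonded interface stays conforming.
#'
#' @param fine_size Fine element size, mm.
#' @param coarse_size Coarse element size, mm.
#' @param focus_halfwidth Half-width of the fine in-plane band, mm.
#' @param fine_height Height of the fine tissue band above the skin, mm.
#' @param dressing_size Target element size across the dressing thickness,
#'   mm (at least 2 elements across).
#' @param mattress_size Mattress element size, mm.
#' @return An object of class `mesh_control`.
#' @export
mesh_control <- function(fine_size = 2, coarse_size = 8,
                         focus_halfwidth = 40, fine_height = 30,
                         dressing_size = 2.75, mattress_size = 9) {
  stopifnot(fine_size > 0, coarse_size >= fine_size, focus_halfwidth > 0,
            fine_height > 0, dressing_size > 0, mattress_size > 0)
  structure(list(fine_size = fine_size, coarse_size = coarse_size,
                 focus_halfwidth = focus_halfwidth,
                 fine_height = fine_height, dressing_size = dressing_size,
                 mattress_size = mattress_size),
            class = "mesh_control")
}

# uniform division of [a, b] at target size h (at least nmin elements)
sized_lines <- function(a, b, h, nmin = 1L) {
  n <- max(nmin, as.integer(round((b - a) / h)))
  seq(a, b, length.out = n + 1L)
}

# graded line set: fine inside [f0, f1], coarse outside
graded_lines <- function(a, b, f0, f1, fine, coarse) {
  f0 <- max(a, f0); f1 <- min(b, f1)
  xs <- sized_lines(f0, f1, fine)
  if (f0 > a) xs <- c(sized_lines(a, f0, coarse)[-length(sized_lines(a, f0, coarse))], xs)
  if (f1 < b) xs <- c(xs, sized_lines(f1, b, coarse)[-1])
  unique(xs)
}

resolve_resolution <- function(resolution) {
  defaults <- c(x = NA, tissue = NA, dressing = NA, mattress = NA, z = NA)
  if (length(resolution) == 1L && is.null(names(resolution))) {
    res <- defaults
    res[] <- resolution
  } else {
    res <- defaults
    res[names(resolution)] <- resolution
    if (anyNA(res[c("x", "tissue", "mattress")])) {
      base <- resolution[[1]]
      res[is.na(res)] <- base
    }
  }
  if (is.na(res["dressing"])) res["dressing"] <- res["tissue"]
  if (is.na(res["z"])) res["z"] <- res["x"]
  if (any(res <= 0)) stop("resolution error: resolution must be > 0",
                          call. = FALSE)
  res
}

layer_divisions <- function(thickness, res, what) {
  n <- as.integer(ceiling(thickness * res))
  if (n < 2L) {
    stop("resolution error: resolution yields fewer than 2 elements across ",
         "the ", what, " layer (", thickness, " mm)", call. = FALSE)
  }
  n
}

in_prominence <- function(x, y, spec, y_tissue_bottom) {
  r <- spec$prominence_tip_radius
  if (r <= 0) return(rep(FALSE, length(x)))
  xc <- spec$tissue_width / 2
  cy <- y_tissue_bottom + spec$prominence_depth + r
  # capsule fully embedded in the tissue: tip circle plus a finite-height
  # body; tissue continues above the bone and rides along with it
  incap <- (x - xc)^2 + (y - cy)^2 <= r^2
  instem <- abs(x - xc) <= r & y >= cy & y <= cy + spec$prominence_height
  incap | instem
}

#' Build a layered mattress / dressing / tissue mesh with an embedded
#' bony prominence
#'
#' Stacks (bottom to top) a mattress, an optional dressing, and a soft-tissue
#' block. The dressing is bonded to the tissue (shared interface nodes — the
#' no-slip bond holds by construction) while the dressing-mattress interface
#' consists of two distinct node sets forming a frictional contact pair. A
#' rounded prominence (region `"bone"`) is embedded in the tissue with its
#' tip facing the dressing.
#'
#' Named node sets produced: `mattress_base`, `mattress_top`,
#' `dressing_bottom` (when a dressing is present), `skin_bottom` (the tissue
#' underside), `dressing_tissue_interface`, `bone_surface`, and `free`.
#'
#' @param spec A [domain_spec()].
#' @param resolution Elements per mm: a scalar, or a named vector with any of
#'   `x`, `tissue`, `dressing`, `mattress`, `z` to set in-plane and per-layer
#'   densities separately. Each layer must receive at least 2 elements across
#'   its thickness.
#' @return A `fea_mesh` with region labels in
#'   `{mattress, dressing, tissue, bone}`.
#' @examples
#' mesh <- build_layered_domain(domain_spec(), resolution = c(
#'   x = 0.2, tissue = 0.2, dressing = 0.4, mattress = 0.12))
#' mesh_quality(mesh)
#' @export
build_layered_domain <- function(spec, resolution = 0.2) {
  stopifnot(inherits(spec, "domain_spec"))
  if (spec$dimensionality == "3D") {
    return(build_layered_domain_3d(spec, resolve_resolution(resolution)))
  }
  W <- spec$tissue_width
  tm <- spec$mattress_thickness
  td <- spec$dressing_thickness
  th <- spec$tissue_height
  if (inherits(resolution, "mesh_control")) {
    mc <- resolution
    xc <- W / 2
    xs <- graded_lines(0, W, xc - mc$focus_halfwidth, xc + mc$focus_halfwidth,
                       mc$fine_size, mc$coarse_size)
    xs_mat <- sized_lines(0, W, mc$mattress_size, nmin = 4L)
    ys_mat <- sized_lines(0, tm, mc$mattress_size, nmin = 2L)
    ys_dre <- function(y0) sized_lines(y0, y0 + td, mc$dressing_size,
                                       nmin = 2L)
    ys_tis <- function(y0) graded_lines(y0, y0 + th, y0, y0 + mc$fine_height,
                                        mc$fine_size, mc$coarse_size)
  } else {
    res <- resolve_resolution(resolution)
    nx <- as.integer(ceiling(W * res["x"]))
    if (nx < 2L) stop("resolution error: fewer than 2 elements across the ",
                      "width", call. = FALSE)
    xs <- seq(0, W, length.out = nx + 1)
    xs_mat <- xs
    nym <- layer_divisions(tm, res["mattress"], "mattress")
    ys_mat <- seq(0, tm, length.out = nym + 1)
    nyt <- layer_divisions(th, res["tissue"], "tissue")
    ys_tis <- function(y0) seq(y0, y0 + th, length.out = nyt + 1)
    if (td > 0) {
      nyd <- layer_divisions(td, res["dressing"], "dressing")
      ys_dre <- function(y0) seq(y0, y0 + td, length.out = nyd + 1)
    }
  }

  mat <- grid_piece(xs_mat, ys_mat, "mattress")
  pieces <- list(mat)
  y_tissue0 <- tm
  dressing_cols <- NULL
  if (td > 0) {
    # snap the dressing footprint to grid lines
    i0 <- which.min(abs(xs - (W - spec$dressing_extent) / 2))
    i1 <- which.min(abs(xs - (W + spec$dressing_extent) / 2))
    if (i1 - i0 < 2L) {
      stop("resolution error: dressing footprint resolves to fewer than 2 ",
           "elements across", call. = FALSE)
    }
    dressing_cols <- i0:i1
    dre <- grid_piece(xs[dressing_cols], ys_dre(tm), "dressing")
    pieces <- c(pieces, list(dre))
    y_tissue0 <- tm + td
  }
  tis <- grid_piece(xs, ys_tis(y_tissue0), "tissue")
  pieces <- c(pieces, list(tis))

  # concatenate pieces with node offsets
  offs <- cumsum(c(0L, vapply(pieces, function(p) nrow(p$nodes), integer(1))))
  nodes <- do.call(rbind, lapply(pieces, `[[`, "nodes"))
  elements <- do.call(rbind, Map(function(p, o) p$elements + o,
                                 pieces, as.list(offs[seq_along(pieces)])))
  region <- unlist(lapply(pieces, `[[`, "region"))
  n_mat_nodes <- nrow(pieces[[1]]$nodes)
  eps <- 1e-9 * max(W, tm + td + th)

  # Fuse dressing-top nodes with coincident tissue-bottom nodes: the no-slip
  # dressing-tissue bond holds by construction. The coincident node pairs at
  # the mattress top (y = tm) are deliberately NOT fused: they form the
  # frictional contact pair.
  if (td > 0) {
    cand <- abs(nodes[, 2] - (tm + td)) < eps
    key <- ifelse(cand, paste0("y", round(nodes[, 1], 9)),
                  paste0("n", seq_len(nrow(nodes))))
    keep <- !duplicated(key)
    # match() against the kept keys returns the compacted index directly
    remap <- match(key, key[keep])
    nodes <- nodes[keep, , drop = FALSE]
    elements[] <- remap[elements]
  }

  ytop <- abs(nodes[, 2] - tm) < eps
  idx <- seq_len(nrow(nodes))
  sets <- list(
    mattress_base = which(abs(nodes[, 2]) < eps),
    mattress_top = which(ytop & idx <= n_mat_nodes)
  )
  if (td > 0) {
    sets$dressing_bottom <- which(ytop & idx > n_mat_nodes)
    sets$skin_bottom <- which(abs(nodes[, 2] - (tm + td)) < eps)
    xlo <- xs[dressing_cols[1]] - eps
    xhi <- xs[dressing_cols[length(dressing_cols)]] + eps
    sets$dressing_tissue_interface <- sets$skin_bottom[
      nodes[sets$skin_bottom, 1] >= xlo & nodes[sets$skin_bottom, 1] <= xhi]
  } else {
    sets$skin_bottom <- which(ytop & idx > n_mat_nodes)
    sets$dressing_tissue_interface <- integer(0)
  }

  # label prominence elements by centroid, then record their nodes
  cx <- rowMeans(matrix(nodes[elements, 1], ncol = 4))
  cy <- rowMeans(matrix(nodes[elements, 2], ncol = 4))
  isbone <- region == "tissue" & in_prominence(cx, cy, spec, y_tissue0)
  region[isbone] <- "bone"
  sets$bone_surface <- sort(unique(as.vector(elements[isbone, ])))
  named <- sort(unique(unlist(sets)))
  sets$free <- setdiff(seq_len(nrow(nodes)), named)

  fea_mesh(nodes, elements, region, sets, depth = spec$effective_depth,
           spec = spec)
}

build_layered_domain_3d <- function(spec, res) {
  # build the 2-D section without merging concerns, then extrude along z
  spec2 <- spec
  spec2$dimensionality <- "2D"
  class(spec2) <- "domain_spec"
  m2 <- build_layered_domain(spec2, res)
  nz <- as.integer(ceiling(spec$tissue_depth * res["z"]))
  if (nz < 2L) stop("resolution error: fewer than 2 elements along depth",
                    call. = FALSE)
  zs <- seq(0, spec$tissue_depth, length.out = nz + 1)
  n2 <- nrow(m2$nodes)
  nodes <- cbind(m2$nodes[rep(seq_len(n2), nz + 1), , drop = FALSE],
                 rep(zs, each = n2))
  e2 <- m2$elements
  elements <- do.call(rbind, lapply(seq_len(nz), function(k) {
    lo <- (k - 1L) * n2
    hi <- k * n2
    cbind(e2 + lo, e2 + hi)
  }))
  region <- rep(m2$region, nz)
  # bone only within a central band: a ridge of half-length 2*tip_radius
  if (spec$prominence_tip_radius > 0) {
    zc <- spec$tissue_depth / 2
    band <- 2 * spec$prominence_tip_radius
    ez <- rowMeans(matrix(nodes[elements, 3], ncol = 8))
    outside <- region == "bone" & abs(ez - zc) > band
    region[outside] <- "tissue"
  }
  sets <- lapply(m2$sets, function(ids) {
    as.integer(outer(ids, (0:nz) * n2, `+`))
  })
  fea_mesh(nodes, elements, region, sets, depth = 1, spec = spec)
}

# ---- quality and volumes ----------------------------------------------------

quad_shape_grad <- function(xi, eta) {
  # dN/dxi (4 x 2) for the bilinear quad on [-1,1]^2, nodes CCW
  cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
        c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
}

hex_shape_grad <- function(xi, eta, zeta) {
  sg <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
              c(-1, -1, 1, 1, -1, -1, 1, 1),
              c(-1, -1, -1, -1, 1, 1, 1, 1))
  N <- function(a) (1 + sg[a, 1] * xi) * (1 + sg[a, 2] * eta) *
    (1 + sg[a, 3] * zeta) / 8
  d <- matrix(0, 8, 3)
  for (a in 1:8) {
    d[a, 1] <- sg[a, 1] * (1 + sg[a, 2] * eta) * (1 + sg[a, 3] * zeta) / 8
    d[a, 2] <- sg[a, 2] * (1 + sg[a, 1] * xi) * (1 + sg[a, 3] * zeta) / 8
    d[a, 3] <- sg[a, 3] * (1 + sg[a, 1] * xi) * (1 + sg[a, 2] * eta) / 8
  }
  d
}

element_jacobians <- function(mesh, points = "all") {
  g <- 1 / sqrt(3)
  if (mesh$dim == 2L) {
    pts <- rbind(expand.grid(xi = c(-g, g), eta = c(-g, g)),
                 if (points == "all") expand.grid(xi = c(-1, 1),
                                                  eta = c(-1, 1)))
    sapply(seq_len(nrow(pts)), function(k) {
      dN <- quad_shape_grad(pts$xi[k], pts$eta[k])
      X <- mesh$nodes
      e <- mesh$elements
      J11 <- rowSums(matrix(X[e, 1], ncol = 4) * rep(dN[, 1], each = nrow(e)))
      J12 <- rowSums(matrix(X[e, 2], ncol = 4) * rep(dN[, 1], each = nrow(e)))
      J21 <- rowSums(matrix(X[e, 1], ncol = 4) * rep(dN[, 2], each = nrow(e)))
      J22 <- rowSums(matrix(X[e, 2], ncol = 4) * rep(dN[, 2], each = nrow(e)))
      J11 * J22 - J12 * J21
    })
  } else {
    pts <- expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g))
    sapply(seq_len(nrow(pts)), function(k) {
      dN <- hex_shape_grad(pts$xi[k], pts$eta[k], pts$zeta[k])
      X <- mesh$nodes
      e <- mesh$elements
      Jc <- array(0, c(nrow(e), 3, 3))
      for (i in 1:3) for (j in 1:3) {
        Jc[, i, j] <- rowSums(matrix(X[e, j], ncol = 8) *
                                rep(dN[, i], each = nrow(e)))
      }
      Jc[, 1, 1] * (Jc[, 2, 2] * Jc[, 3, 3] - Jc[, 2, 3] * Jc[, 3, 2]) -
        Jc[, 1, 2] * (Jc[, 2, 1] * Jc[, 3, 3] - Jc[, 2, 3] * Jc[, 3, 1]) +
        Jc[, 1, 3] * (Jc[, 2, 1] * Jc[, 3, 2] - Jc[, 2, 2] * Jc[, 3, 1])
    })
  }
}

#' Mesh quality report
#'
#' Reports the minimum scaled Jacobian over all quadrature points and element
#' corners (1 for a square/cube; <= 0 flags a degenerate or inverted
#' element), the maximum edge-length aspect ratio, and the counts. Inverted
#' elements do not raise; the caller inspects `min_jacobian`.
#'
#' @param mesh A `fea_mesh`.
#' @return A tibble with columns `min_jacobian`, `max_aspect_ratio`,
#'   `element_count`, `node_count`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "fea_mesh"))
  detJ <- element_jacobians(mesh, points = "all")
  if (is.null(dim(detJ))) detJ <- matrix(detJ, nrow = 1)
  # reference measure: |element| / reference-cell measure
  vol <- element_volumes(mesh)
  ref <- if (mesh$dim == 2L) 4 else 8
  scaled <- detJ / pmax(abs(vol) / ref, .Machine$double.eps)
  npe <- ncol(mesh$elements)
  e <- mesh$elements
  X <- mesh$nodes
  edges <- if (mesh$dim == 2L) {
    cbind(1:4, c(2:4, 1))
  } else {
    rbind(cbind(1:4, c(2:4, 1)), cbind(5:8, c(6:8, 5)), cbind(1:4, 5:8))
  }
  len2 <- sapply(seq_len(nrow(edges)), function(k) {
    a <- e[, edges[k, 1]]
    b <- e[, edges[k, 2]]
    rowSums((X[a, , drop = FALSE] - X[b, , drop = FALSE])^2)
  })
  if (is.null(dim(len2))) len2 <- matrix(len2, nrow = 1)
  aspect <- sqrt(apply(len2, 1, max) / pmax(apply(len2, 1, min),
                                            .Machine$double.eps))
  tibble::tibble(min_jacobian = min(scaled),
                 max_aspect_ratio = max(aspect),
                 element_count = nrow(e),
                 node_count = nrow(X))
}

#' Per-element volumes (or areas per unit depth in 2-D)
#'
#' Reference volumes by default; deformed volumes when a nodal displacement
#' field is supplied. 2-D values are areas times a unit (1 mm) out-of-plane
#' thickness.
#'
#' @param mesh A `fea_mesh`.
#' @param displacement Optional numeric matrix (nodes x dim) of nodal
#'   displacements, mm.
#' @return Numeric vector of strictly positive per-element volumes
#'   (mm^3, or mm^2 x 1 mm in 2-D). An inverted deformed element raises an
#'   error naming the element.
#' @export
element_volumes <- function(mesh, displacement = NULL) {
  stopifnot(inherits(mesh, "fea_mesh"))
  X <- mesh$nodes
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    if (!all(dim(displacement) == dim(X))) {
      stop("displacement must supply one vector per node", call. = FALSE)
    }
    X <- X + displacement
  }
  e <- mesh$elements
  if (mesh$dim == 2L) {
    x <- matrix(X[e, 1], ncol = 4)
    y <- matrix(X[e, 2], ncol = 4)
    # signed shoelace area of the straight-sided quadrilateral
    v <- 0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
                  (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
                  (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
                  (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
  } else {
    m2 <- mesh
    m2$nodes <- X
    v <- rowSums(element_jacobians(m2, points = "gauss"))
  }
  if (!is.null(displacement) && any(v <= 0)) {
    stop("inverted deformed element(s): ",
         paste(utils::head(which(v <= 0), 5), collapse = ", "), call. = FALSE)
  }
  v
}
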