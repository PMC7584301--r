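# Node-to-surface penalty contact with Coulomb friction.
#
# Slave nodes (e.g. the dressing underside) are checked against a piecewise
# linear master surface (e.g. the mattress top) in the deformed
# configuration. Penetration is resisted by a normal penalty spring per
# slave node; friction uses an elastic-stick tangential spring with a
# return map onto the Coulomb cone |t_T| <= mu * N. Stick anchors are fixed
# during a load step (consistent stick stiffness) and committed - with the
# slip return map applied - when the step converges.

#' Specify a frictional contact pair
#'
#' @param slave Name of the node set acting as slave (penetrating) surface.
#' @param master Name of the node set acting as master surface; its nodes
#'   are ordered by reference x to form a polyline.
#' @param friction_coefficient Coulomb friction coefficient mu >= 0
#'   (default 0.4, a somewhat sticky foam-foam interface).
#' @param normal_penalty Normal penalty stiffness, kPa/mm (pressure per unit
#'   penetration). `NULL` selects 50x the softer neighbour's Young's modulus
#'   per master element length at solve time.
#' @param tangential_penalty Tangential penalty stiffness, kPa/mm; defaults
#'   to a tenth of the normal penalty (a softer stick spring regularizes the
#'   stick-slip transition without visibly changing the transmitted
#'   traction).
#' @return An object of class `contact_spec`.
#' @export
contact_spec <- function(slave, master, friction_coefficient = 0.4,
                         normal_penalty = NULL, tangential_penalty = NULL) {
  if (friction_coefficient < 0) stop("friction coefficient must be >= 0",
                                     call. = FALSE)
  if (!is.null(normal_penalty) && normal_penalty <= 0) {
    stop("normal_penalty must be > 0", call. = FALSE)
  }
  structure(list(slave = slave, master = master,
                 mu = friction_coefficient,
                 normal_penalty = normal_penalty,
                 tangential_penalty = tangential_penalty),
            class = "contact_spec")
}

default_contact_penalty <- function(mesh, materials, cs) {
  # 50x the softer neighbouring modulus per unit master element length
  Es <- vapply(materials[!vapply(materials, is.null, logical(1))],
               function(m) m$constants$E, numeric(1))
  soft <- min(Es)
  mids <- mesh$sets[[cs$master]]
  xs <- sort(mesh$nodes[mids, 1])
  h <- stats::median(diff(xs))
  50 * soft / h
}

# Geometry of all slave nodes of one pair against the deformed master
# polyline: segment index, local coordinate, gap, arclength, tangent/normal.
project_slaves <- function(mesh, u, cs) {
  um <- matrix(u, ncol = 2, byrow = TRUE)
  x <- mesh$nodes + um
  mids <- mesh$sets[[cs$master]]
  mids <- mids[order(mesh$nodes[mids, 1])]
  xm <- x[mids, , drop = FALSE]
  slaves <- mesh$sets[[cs$slave]]
  if (is.null(slaves) || !length(slaves)) {
    stop("contact slave set '", cs$slave, "' not found or empty",
         call. = FALSE)
  }
  segx <- diff(xm[, 1]); segy <- diff(xm[, 2])
  L <- sqrt(segx^2 + segy^2)
  cumL <- c(0, cumsum(L))
  # smoothed nodal normals (averaged facet normals) interpolated along each
  # segment keep the contact force direction continuous when a slave node's
  # projection crosses a master node - facet normals alone cause Newton
  # limit cycles at the kinks
  fn <- cbind(-segy / L, segx / L) # facet normals, upward
  nn <- rbind(fn[1, ], (fn[-nrow(fn), ] + fn[-1, ]) / 2, fn[nrow(fn), ])
  nn <- nn / sqrt(rowSums(nn^2))
  # tributary length per slave node from reference spacing
  sx <- mesh$nodes[slaves, 1]
  os <- order(sx)
  trib <- rep(1, length(slaves))
  if (length(slaves) > 1) {
    d <- diff(sx[os])
    trib[os] <- (c(d[1], d) + c(d, d[length(d)])) / 2
  }
  out <- vector("list", length(slaves))
  for (q in seq_along(slaves)) {
    s <- slaves[q]
    xs <- x[s, ]
    k <- findInterval(xs[1], xm[, 1], all.inside = TRUE)
    tseg <- c(segx[k], segy[k]) / L[k]
    xi <- sum((xs - xm[k, ]) * tseg) / L[k]
    xi <- min(max(xi, 0), 1)
    n <- (1 - xi) * nn[k, ] + xi * nn[k + 1, ]
    n <- n / sqrt(sum(n^2))
    t <- c(n[2], -n[1]) # right-handed: points along increasing x
    xp <- xm[k, ] + xi * (xm[k + 1, ] - xm[k, ])
    out[[q]] <- list(node = s, seg = k, xi = xi, t = t, n = n,
                     g = sum((xs - xp) * n),
                     sarc = cumL[k] + xi * L[k],
                     m1 = mids[k], m2 = mids[k + 1], trib = trib[q])
  }
  out
}

#' Initialize the friction state of contact pairs
#'
#' Anchors every slave node's stick reference at the master material point
#' (segment index + local coordinate) it currently projects onto.
#'
#' @keywords internal
init_contact_state <- function(mesh, contacts, u = NULL) {
  if (is.null(u)) u <- numeric(2L * nrow(mesh$nodes))
  lapply(contacts, function(cs) {
    prj <- project_slaves(mesh, u, cs)
    list(nodes = vapply(prj, `[[`, integer(1), "node"),
         aseg = vapply(prj, `[[`, integer(1), "seg"),
         axi = vapply(prj, `[[`, numeric(1), "xi"),
         active = rep(FALSE, length(prj)),
         tT = rep(0, length(prj)), N = rep(0, length(prj)),
         dissipation = 0)
  })
}

# advance an anchor (segment, xi) by arc ds along the deformed master
advance_anchor <- function(k0, xi0, ds, L) {
  cum <- c(0, cumsum(L))
  s <- cum[k0] + xi0 * L[k0] + ds
  s <- min(max(s, 0), cum[length(cum)])
  k <- findInterval(s, cum, all.inside = TRUE)
  list(seg = as.integer(k), xi = (s - cum[k]) / L[k])
}

contact_assemble_all <- function(mesh, materials, u, contacts, state,
                                 want_tangent) {
  ndof <- 2L * nrow(mesh$nodes)
  r <- numeric(ndof)
  ti <- tj <- tx <- numeric(0)
  info <- list()
  for (p in seq_along(contacts)) {
    cs <- contacts[[p]]
    kN <- cs$normal_penalty %||% default_contact_penalty(mesh, materials, cs)
    kT <- cs$tangential_penalty %||% (kN / 10)
    res <- contact_assemble_pair(mesh, u, cs, state[[p]], kN, kT, want_tangent)
    r <- r + res$r
    state[[p]] <- res$state
    info[[p]] <- res$info
    if (want_tangent) {
      ti <- c(ti, res$ti); tj <- c(tj, res$tj); tx <- c(tx, res$tx)
    }
  }
  list(r = r, state = state, info = info,
       triplets = if (want_tangent) list(i = ti, j = tj, x = tx) else NULL)
}

contact_assemble_pair <- function(mesh, u, cs, st, kN, kT, want_tangent) {
  prj <- project_slaves(mesh, u, cs)
  um <- matrix(u, ncol = 2, byrow = TRUE)
  x <- mesh$nodes + um
  mids <- mesh$sets[[cs$master]]
  mids <- mids[order(mesh$nodes[mids, 1])]
  xm <- x[mids, , drop = FALSE]
  L <- sqrt(diff(xm[, 1])^2 + diff(xm[, 2])^2)
  ndof <- 2L * nrow(mesh$nodes)
  r <- numeric(ndof)
  nq <- length(prj)
  # preallocated triplet store: two 6x6 dof blocks (72 entries) per slave
  ti <- tj <- tx <- numeric(72L * nq)
  ntrip <- 0L
  newN <- newT <- numeric(nq)
  active <- logical(nq)
  aseg <- st$aseg
  axi <- st$axi
  diss <- 0
  for (q in seq_len(nq)) {
    p <- prj[[q]]
    if (p$g > 0) { # open: no force; re-anchor at the current projection
      aseg[q] <- p$seg
      axi[q] <- p$xi
      next
    }
    active[q] <- TRUE
    ls <- p$trib
    # Near-C1 activation: the normal force blends in quadratically over the
    # first `gs` of penetration (removes Newton limit cycles from
    # marginally active nodes) with a small residual slope `del * kN` at
    # touch so a body resting at exactly zero gap is never stiffness-free
    gs <- 2e-3
    del <- 0.05
    pen <- -p$g
    if (pen < gs) {
      N <- kN * ls * ((1 - del) * pen^2 / (2 * gs) + del * pen)
      kN_eff <- kN * ((1 - del) * pen / gs + del)
    } else {
      N <- kN * ls * (pen - (1 - del) * gs / 2)
      kN_eff <- kN
    }
    # stick: elastic spring between the slave and its anchored master
    # material point, acting along the (frozen) tangent direction
    k0 <- st$aseg[q]
    xi0 <- st$axi[q]
    xanch <- xm[k0, ] + xi0 * (xm[k0 + 1, ] - xm[k0, ])
    tT <- -kT * ls * sum((x[st$nodes[q], ] - xanch) * p$t)
    slip <- abs(tT) > cs$mu * N
    if (slip) {
      tTs <- sign(tT) * cs$mu * N
      ds <- -(tT - tTs) / (kT * ls) # anchor advance resolving the excess
      adv <- advance_anchor(k0, xi0, ds, L)
      aseg[q] <- adv$seg
      axi[q] <- adv$xi
      diss <- diss + abs(tTs * ds)
      tT <- tTs
    } else {
      aseg[q] <- k0
      axi[q] <- xi0
    }
    newN[q] <- N
    newT[q] <- tT
    # normal force block (projection segment)
    nds_n <- c(p$node, mids[p$seg], mids[p$seg + 1])
    w_n <- c(1, -(1 - p$xi), -p$xi)
    # tangential force block (anchor segment)
    nds_t <- c(p$node, mids[k0], mids[k0 + 1])
    w_t <- c(1, -(1 - xi0), -xi0)
    for (a in 1:3) {
      r[c(2L * nds_n[a] - 1L, 2L * nds_n[a])] <-
        r[c(2L * nds_n[a] - 1L, 2L * nds_n[a])] - w_n[a] * N * p$n
      r[c(2L * nds_t[a] - 1L, 2L * nds_t[a])] <-
        r[c(2L * nds_t[a] - 1L, 2L * nds_t[a])] - w_t[a] * tT * p$t
    }
    if (want_tangent) {
      # 6x6 dof blocks: outer product of weight/dof patterns with a 2x2 core
      dofs_n <- as.vector(rbind(2L * nds_n - 1L, 2L * nds_n))
      dofs_t <- as.vector(rbind(2L * nds_t - 1L, 2L * nds_t))
      wv_n <- rep(w_n, each = 2)
      wv_t <- rep(w_t, each = 2)
      Mn <- kN_eff * ls * (p$n %o% p$n)
      Mt <- if (slip) {
        cs$mu * sign(tT) * kN_eff * ls * (p$t %o% p$n)
      } else {
        kT * ls * (p$t %o% p$t)
      }
      comp <- rep(1:2, 3)
      ia <- rep(1:6, times = 6)
      ib <- rep(1:6, each = 6)
      sl <- ntrip + 1:36
      ti[sl] <- dofs_n[ia]; tj[sl] <- dofs_n[ib]
      tx[sl] <- wv_n[ia] * wv_n[ib] * Mn[cbind(comp[ia], comp[ib])]
      sl <- ntrip + 37:72
      if (slip) {
        # rows on the anchor block, columns on the projection block
        ti[sl] <- dofs_t[ia]; tj[sl] <- dofs_n[ib]
        tx[sl] <- wv_t[ia] * wv_n[ib] * Mt[cbind(comp[ia], comp[ib])]
      } else {
        ti[sl] <- dofs_t[ia]; tj[sl] <- dofs_t[ib]
        tx[sl] <- wv_t[ia] * wv_t[ib] * Mt[cbind(comp[ia], comp[ib])]
      }
      ntrip <- ntrip + 72L
    }
  }
  ti <- ti[seq_len(ntrip)]; tj <- tj[seq_len(ntrip)]; tx <- tx[seq_len(ntrip)]
  list(r = r, ti = ti, tj = tj, tx = tx,
       state = list(nodes = st$nodes, aseg = aseg, axi = axi, active = active,
                    tT = newT, N = newN, dissipation = diss),
       info = tibble::tibble(node = st$nodes, active = active,
                             normal_force = newN, tangential_force = newT))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
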