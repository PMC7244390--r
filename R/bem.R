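#' Signed solid angle of a triangle
#'
#' Analytic signed solid angle subtended by triangle (a, b, c) at each
#' observation point (van Oosterom & Strackee). With counter-clockwise
#' vertex order seen from outside (outward normal), interior points of a
#' closed surface accumulate a total of +4*pi.
#'
#' @param points p x 3 observation points.
#' @param a,b,c triangle vertices (3-vectors).
#' @return numeric vector of solid angles (steradians, signed).
#' @export
triangle_solid_angle <- function(points, a, b, c) {
  points <- rbind(points)
  y1 <- sweep(points, 2L, a, `-`) * -1
  y2 <- sweep(points, 2L, b, `-`) * -1
  y3 <- sweep(points, 2L, c, `-`) * -1
  n1 <- sqrt(rowSums(y1^2)); n2 <- sqrt(rowSums(y2^2)); n3 <- sqrt(rowSums(y3^2))
  triple <- y1[, 1L] * (y2[, 2L] * y3[, 3L] - y2[, 3L] * y3[, 2L]) +
    y1[, 2L] * (y2[, 3L] * y3[, 1L] - y2[, 1L] * y3[, 3L]) +
    y1[, 3L] * (y2[, 1L] * y3[, 2L] - y2[, 2L] * y3[, 1L])
  den <- n1 * n2 * n3 + rowSums(y1 * y2) * n3 +
    rowSums(y1 * y3) * n2 + rowSums(y2 * y3) * n1
  2 * atan2(triple, den)
}

#' Linearly weighted solid-angle integrals of a triangle
#'
#' Analytic integrals `I_i = int_T psi_i(r') dOmega(r')` of the three linear
#' (barycentric) shape functions of triangle (a, b, c) against the
#' solid-angle kernel, for each observation point. The three columns sum to
#' the triangle's solid angle. Observation points in the triangle's plane
#' (including its own vertices) yield zeros.
#'
#' @inheritParams triangle_solid_angle
#' @return p x 3 matrix of weighted solid angles.
#' @export
triangle_linear_weights <- function(points, a, b, c) {
  points <- rbind(points)
  e1 <- b - a
  e2 <- c - a
  nvec <- crossv(e1, e2)
  two_area <- sqrt(sum(nvec^2))
  nhat <- nvec / two_area
  om <- triangle_solid_angle(points, a, b, c)
  d <- (a[1L] - points[, 1L]) * nhat[1L] + (a[2L] - points[, 2L]) * nhat[2L] +
    (a[3L] - points[, 3L]) * nhat[3L]
  # J1 = nhat * Omega - sum_edges mhat_e * int_e dl / r
  J1 <- cbind(nhat[1L] * om, nhat[2L] * om, nhat[3L] * om)
  verts <- list(a, b, c)
  for (k in 1:3) {
    va <- verts[[k]]
    vb <- verts[[if (k == 3L) 1L else k + 1L]]
    ehat <- (vb - va) / sqrt(sum((vb - va)^2))
    ya <- sweep(points, 2L, va, `-`) * -1
    yb <- sweep(points, 2L, vb, `-`) * -1
    na_ <- sqrt(rowSums(ya^2)); nb_ <- sqrt(rowSums(yb^2))
    Le <- log((nb_ + yb %*% ehat) / (na_ + ya %*% ehat))
    mhat <- crossv(ehat, nhat)
    J1 <- J1 - cbind(mhat[1L] * Le, mhat[2L] * Le, mhat[3L] * Le)
  }
  out <- matrix(0, nrow(points), 3L)
  opp <- list(c(3L, 2L), c(1L, 3L), c(2L, 1L))
  for (i in 1:3) {
    vi <- verts[[opp[[i]][2L]]]   # edge opposite vertex i runs vi -> vj
    vj <- verts[[opp[[i]][1L]]]
    vv <- vj - vi
    bi <- crossv(nhat, vv) / two_area
    ai <- -sum(nhat * crossv(vv, vi)) / two_area
    # psi_i at the observation point's in-plane projection, times Omega,
    # plus the first-moment correction
    out[, i] <- (ai + points %*% bi) * om + d * (J1 %*% bi)
  }
  out[!is.finite(rowSums(out)), ] <- 0
  out
}

#' Assemble a boundary-element model of the layered conductor
#'
#' Linear-collocation boundary-element discretization of the surface
#' potential integral equation for a piecewise homogeneous conductor:
#' potentials live at mesh vertices, each triangle's analytically computed
#' solid angle is distributed to its three vertices, the own-surface
#' diagonal is corrected so that constant potentials are in the null space
#' (auto solid angle), and the singular system is deflated against the
#' constant mode. With `isolated_skull = TRUE` (recommended for
#' sigma_skull << sigma_brain) the isolated-skull approach is used: the
#' potential of the brain compartment closed by an insulating skull is
#' solved first on the innermost boundary and the full system solves only
#' the correction.
#'
#' @param head a [head_model()] with `boundary_meshes` (inner skull, outer
#'   skull, scalp; closed, nested, outward-oriented).
#' @param isolated_skull logical; use the isolated-skull approach.
#' @return An object of class `cereb_bem` holding factorized operators.
#' @export
bem_model <- function(head, isolated_skull = TRUE) {
  meshes <- head$boundary_meshes
  if (is.null(meshes))
    stop("head model carries no boundary meshes; supply them via ",
         "head_model(boundary_meshes = ...)")
  for (m in meshes) {
    if (!is_closed_mesh(m)) stop("BEM boundary meshes must be closed")
  }
  sig <- head$conductivities
  sig_in <- sig
  sig_out <- c(sig[2L], sig[3L], 0)
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1L))
  offs <- c(0L, cumsum(nv))
  N <- sum(nv)
  allv <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  surf_of <- rep(seq_along(meshes), nv)
  D <- matrix(0, N, N)
  for (j in seq_along(meshes)) {
    mj <- meshes[[j]]
    f <- mj$faces
    for (t in seq_len(nrow(f))) {
      tri <- f[t, ] + offs[j]
      om <- triangle_linear_weights(allv, allv[tri[1L], ], allv[tri[2L], ],
                                    allv[tri[3L], ])
      D[, tri[1L]] <- D[, tri[1L]] + om[, 1L]
      D[, tri[2L]] <- D[, tri[2L]] + om[, 2L]
      D[, tri[3L]] <- D[, tri[3L]] + om[, 3L]
    }
  }
  # auto solid angle: own-surface row totals must equal 2*pi
  for (i in seq_along(meshes)) {
    idx <- (offs[i] + 1L):offs[i + 1L]
    row_tot <- rowSums(D[idx, idx, drop = FALSE])
    D[cbind(idx, idx)] <- D[cbind(idx, idx)] + (2 * pi - row_tot)
  }
  half <- (sig_in + sig_out)[surf_of] / 2
  sdiff_col <- (sig_in - sig_out)[surf_of]
  M <- -sweep(D, 2L, sdiff_col, `*`) / (4 * pi)
  diag(M) <- diag(M) + half
  c0 <- mean(half)
  Mdefl <- M + c0 / N
  solver <- solve(Mdefl)
  iso <- NULL
  if (isolated_skull) {
    idx1 <- (offs[1L] + 1L):offs[2L]
    D11 <- D[idx1, idx1, drop = FALSE]
    Miso <- sig[1L] * (diag(length(idx1)) / 2 - D11 / (4 * pi))
    Miso_defl <- Miso + (sig[1L] / 2) / length(idx1)
    iso <- list(solver = solve(Miso_defl), idx = idx1, M_cols = M[, idx1])
  }
  structure(list(head = head, meshes = meshes, vertices = allv,
                 surf_of = surf_of, offsets = offs, solver = solver,
                 iso = iso, sig_in = sig_in, sig_out = sig_out),
            class = "cereb_bem")
}

# Infinite-medium source term sigma0 * V_inf at the collocation vertices
# (the 1/sigma0 of V_inf cancels, so this is conductivity-free).
bem_source_term <- function(bem, dipole_pos, dipole_mom) {
  nd <- nrow(dipole_pos)
  s <- matrix(0, nrow(bem$vertices), nd)
  for (k in seq_len(nd)) {
    d <- sweep(bem$vertices, 2L, dipole_pos[k, ])
    s[, k] <- (d %*% dipole_mom[k, ]) / (rowSums(d^2))^1.5 / (4 * pi)
  }
  s
}

# Surface potentials at all boundary vertices for each dipole (N x nd).
bem_surface_potentials <- function(bem, dipole_pos, dipole_mom) {
  dipole_pos <- rbind(dipole_pos)
  dipole_mom <- rbind(dipole_mom)
  s <- bem_source_term(bem, dipole_pos, dipole_mom)
  if (is.null(bem$iso)) return(bem$solver %*% s)
  v_iso <- bem$iso$solver %*% s[bem$iso$idx, , drop = FALSE]
  s_mod <- s - bem$iso$M_cols %*% v_iso
  v <- bem$solver %*% s_mod
  v[bem$iso$idx, ] <- v[bem$iso$idx, ] + v_iso
  v
}

# Barycentric interpolation weights of points projected onto a mesh
# (nearest triangle by ray through the origin direction). Returns a
# p x nv sparse weight matrix.
mesh_barycentric_weights <- function(mesh, points) {
  points <- rbind(points)
  np <- nrow(points)
  f <- mesh$faces
  v <- mesh$vertices
  ti <- tj <- tx <- vector("list", np)
  fn <- face_normals(mesh)
  for (p in seq_len(np)) {
    pt <- points[p, ]
    best <- NULL; best_score <- -Inf
    for (t in seq_len(nrow(f))) {
      a <- v[f[t, 1L], ]; b <- v[f[t, 2L], ]; c_ <- v[f[t, 3L], ]
      n <- fn[t, ]
      denom <- sum(pt * n)
      if (abs(denom) < 1e-300) next
      scale <- sum(a * n) / denom   # ray from origin through pt
      if (scale <= 0) next          # triangle on the far side of the shell
      q <- pt * scale
      v0 <- b - a; v1 <- c_ - a; v2 <- q - a
      d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
      d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
      den <- d00 * d11 - d01 * d01
      bv <- (d11 * d20 - d01 * d21) / den
      bw <- (d00 * d21 - d01 * d20) / den
      score <- min(bv, bw, 1 - bv - bw)
      if (score > best_score) {
        best_score <- score
        best <- list(tri = t, w = c(1 - bv - bw, bv, bw))
      }
      if (best_score >= 0) break
    }
    wcl <- pmax(best$w, 0)
    wcl <- wcl / sum(wcl)
    ti[[p]] <- rep(p, 3L)
    tj[[p]] <- f[best$tri, ]
    tx[[p]] <- wcl
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(np, nrow(v)))
}

#' Boundary-element forward solution
#'
#' Computes the gain matrix of the given dipoles for a mixed sensor array
#' using the linear-collocation BEM: EEG potentials are read at the
#' electrodes by barycentric interpolation on the scalp mesh; the magnetic
#' field is the primary-current (infinite medium) field plus the
#' volume-current correction, a boundary integral of the computed surface
#' potentials (centroid quadrature per triangle).
#'
#' @param dipole_pos n x 3 dipole positions, meters (inside the innermost
#'   mesh, at least 5 mm by convention).
#' @param dipole_mom n x 3 dipole moments, A m.
#' @param sensors a `cereb_sensor_array`.
#' @param bem a [bem_model()] (or a [head_model()] with boundary meshes).
#' @return M x n gain matrix; rows follow `sensors$channels` (T for
#'   magnetometers, T/m for gradiometers, V unreferenced for electrodes).
#' @export
bem_forward <- function(dipole_pos, dipole_mom, sensors, bem) {
  if (inherits(bem, "cereb_head_model")) bem <- bem_model(bem)
  dipole_pos <- rbind(dipole_pos)
  dipole_mom <- rbind(dipole_mom)
  V <- bem_surface_potentials(bem, dipole_pos, dipole_mom)
  ch <- sensors$channels
  G <- matrix(0, nrow(ch), nrow(dipole_pos))
  is_el <- ch$type == "electrode"
  if (any(is_el)) {
    scalp <- bem$meshes[[length(bem$meshes)]]
    idx <- (bem$offsets[length(bem$meshes)] + 1L):bem$offsets[length(bem$meshes) + 1L]
    W <- mesh_barycentric_weights(scalp, as.matrix(ch[is_el, c("x", "y", "z")]))
    G[is_el, ] <- as.matrix(W %*% V[idx, , drop = FALSE])
  }
  # triangle geometry for the volume-current integral
  tri_area <- c(); tri_ctr <- NULL; tri_n <- NULL; tri_sdiff <- c()
  tri_verts <- NULL
  for (j in seq_along(bem$meshes)) {
    mj <- bem$meshes[[j]]
    fa <- face_areas(mj); fn <- face_normals(mj)
    ctr <- (mj$vertices[mj$faces[, 1L], ] + mj$vertices[mj$faces[, 2L], ] +
              mj$vertices[mj$faces[, 3L], ]) / 3
    tri_area <- c(tri_area, fa)
    tri_ctr <- rbind(tri_ctr, ctr)
    tri_n <- rbind(tri_n, fn)
    tri_sdiff <- c(tri_sdiff, rep(bem$sig_in[j] - bem$sig_out[j],
                                  nrow(mj$faces)))
    tri_verts <- rbind(tri_verts, mj$faces + bem$offsets[j])
  }
  Vbar <- (V[tri_verts[, 1L], , drop = FALSE] + V[tri_verts[, 2L], , drop = FALSE] +
             V[tri_verts[, 3L], , drop = FALSE]) / 3
  meg_rows <- which(!is_el)
  if (length(meg_rows)) {
    pos <- as.matrix(ch[, c("x", "y", "z")])
    ori <- as.matrix(ch[, c("ox", "oy", "oz")])
    tang <- as.matrix(ch[, c("tx", "ty", "tz")])
    bl <- ch$baseline_mm / 1000
    bem_field_comp <- function(p, o) {
      # primary field component
      prim <- numeric(ncol(V))
      for (k in seq_len(nrow(dipole_pos))) {
        d <- p - dipole_pos[k, ]
        Bp <- MU0_OVER_4PI * crossv(dipole_mom[k, ], d) / sum(d^2)^1.5
        prim[k] <- sum(Bp * o)
      }
      rr <- sweep(-tri_ctr, 2L, -p)         # p - centroid
      cx <- cbind(tri_n[, 2L] * rr[, 3L] - tri_n[, 3L] * rr[, 2L],
                  tri_n[, 3L] * rr[, 1L] - tri_n[, 1L] * rr[, 3L],
                  tri_n[, 1L] * rr[, 2L] - tri_n[, 2L] * rr[, 1L])
      w <- MU0_OVER_4PI * tri_sdiff * tri_area * (cx %*% o) / rowSums(rr^2)^1.5
      prim - as.numeric(t(w) %*% Vbar)
    }
    for (r in meg_rows) {
      if (ch$type[r] == "magnetometer") {
        G[r, ] <- bem_field_comp(pos[r, ], ori[r, ])
      } else {
        sh <- tang[r, ] * bl[r] / 2
        G[r, ] <- (bem_field_comp(pos[r, ] + sh, ori[r, ]) -
                     bem_field_comp(pos[r, ] - sh, ori[r, ])) / bl[r]
      }
    }
  }
  G
}

crossv <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
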