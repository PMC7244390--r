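MU0_OVER_4PI <- 1e-7  # T m / A

#' Magnetic field of a current dipole in a spherically symmetric conductor
#'
#' Closed-form (Sarvas) magnetic field outside a spherically symmetric
#' conductor. The field is independent of the conductivity profile; radial
#' dipoles and dipoles at the sphere center are silent.
#'
#' @param dipole_pos n x 3 dipole positions, meters.
#' @param dipole_mom n x 3 dipole moments, A m.
#' @param points p x 3 exterior field points, meters. Every point must be
#'   farther from the center than every dipole.
#' @param center sphere center, meters.
#' @return If one dipole is given, a p x 3 matrix of fields (Tesla); if one
#'   point is given, an n x 3 matrix of per-dipole fields.
#' @export
meg_field_sphere <- function(dipole_pos, dipole_mom, points,
                             center = c(0, 0, 0)) {
  dipole_pos <- rbind(dipole_pos)
  dipole_mom <- rbind(dipole_mom)
  points <- rbind(points)
  if (nrow(points) == 1L)
    return(sarvas_field_at_point(dipole_pos, dipole_mom,
                                 as.numeric(points), center))
  if (nrow(dipole_pos) != 1L)
    stop("either a single dipole with many points or a single point with ",
         "many dipoles is supported")
  out <- matrix(NA_real_, nrow(points), 3L)
  for (i in seq_len(nrow(points)))
    out[i, ] <- sarvas_field_at_point(dipole_pos, dipole_mom,
                                      points[i, ], center)
  out
}

# Vectorized over dipoles for a fixed field point.
sarvas_field_at_point <- function(r0, Q, point, center) {
  r_ <- point - center
  R <- sqrt(sum(r_^2))
  r0_ <- sweep(rbind(r0), 2L, center)
  src_rad <- sqrt(rowSums(r0_^2))
  if (any(src_rad >= R))
    stop("field point at radius ", signif(R, 6),
         " m lies inside the source radius ", signif(max(src_rad), 6), " m")
  a <- sweep(-r0_, 2L, -r_)                 # r - r0
  an <- sqrt(rowSums(a^2))
  adotr <- a %*% r_
  FF <- an * (R * an + R^2 - r0_ %*% r_)
  cf1 <- an^2 / R + adotr / an + 2 * an + 2 * R
  cf2 <- an + 2 * R + adotr / an
  gradF <- cf1 %*% rbind(r_) - as.vector(cf2) * r0_
  QxR0 <- cbind(Q[, 2L] * r0_[, 3L] - Q[, 3L] * r0_[, 2L],
                Q[, 3L] * r0_[, 1L] - Q[, 1L] * r0_[, 3L],
                Q[, 1L] * r0_[, 2L] - Q[, 2L] * r0_[, 1L])
  MU0_OVER_4PI * (as.vector(FF) * QxR0 -
                    as.vector(QxR0 %*% r_) * gradF) / as.vector(FF)^2
}

# Radial transfer factors for the concentric three-shell conductor.
# Returns T_n such that the scalp-surface potential is
#   V = 1/(4 pi sigma1 r3^2) * sum_n T_n (b/r3)^(n-1)
#       [ n q_r P_n(c) + (q.re - c q.r0hat) P_n'(c) ].
# Radii are scaled by the scalp radius for conditioning.
three_shell_transfer <- function(head, n_terms) {
  rr <- head$shell_radii / head$shell_radii[3L]
  s <- head$conductivities
  n_lay <- length(rr)
  out <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    # In each layer u(rho) = A rho^n + B rho^-(n+1). Work with
    # X = A * rho_if^(2n+1), Y = B at each interface rho_if and propagate
    # inward from the air boundary (sigma du/drho = 0 at rho = 1), which
    # keeps every quantity O(1) at any harmonic degree.
    X <- 1
    Y <- n / (n + 1)
    rho_prev <- 1
    for (k in seq(n_lay - 1L, 1L)) {
      rho <- rr[k]
      t_ <- s[k + 1L] / s[k]
      Xo <- X * (rho / rho_prev)^(2 * n + 1)
      Yo <- Y
      X <- ((n + 1) * (Xo + Yo) + t_ * (n * Xo - (n + 1) * Yo)) / (2 * n + 1)
      Y <- (n * (Xo + Yo) - t_ * (n * Xo - (n + 1) * Yo)) / (2 * n + 1)
      rho_prev <- rho
    }
    B <- Y
    # Interior solution: source term rho^-(n+1) (unit coefficient) plus a
    # regular part; matching fixes the overall scale through B.
    out[n] <- (1 + n / (n + 1)) / B
  }
  out
}

#' Scalp potential of current dipoles in a concentric three-shell head
#'
#' Legendre-series solution for the electric potential on the scalp surface
#' of a three-compartment (brain/skull/scalp) concentric spherical
#' conductor. The series is truncated adaptively once the tail contributes
#' less than `tol` relative to the accumulated potential.
#'
#' @param dipole_pos n x 3 dipole positions, meters (inside the brain
#'   shell).
#' @param dipole_mom n x 3 dipole moments, A m.
#' @param electrodes m x 3 electrode positions on the scalp sphere, meters.
#' @param head a [head_model()].
#' @param tol relative tail tolerance for series truncation.
#' @param max_terms maximum number of harmonics before a non-convergence
#'   error.
#' @return m x n matrix of potentials, Volts (unreferenced).
#' @export
eeg_potential_spheres <- function(dipole_pos, dipole_mom, electrodes, head,
                                  tol = 1e-8, max_terms = 400L) {
  dipole_pos <- rbind(dipole_pos)
  dipole_mom <- rbind(dipole_mom)
  electrodes <- rbind(electrodes)
  r3 <- head$shell_radii[3L] / 1000
  e_ <- sweep(electrodes, 2L, head$center)
  er <- sqrt(rowSums(e_^2))
  if (any(abs(er - r3) > 1e-6 * r3))
    stop("electrodes must lie on the scalp sphere (radius ", r3, " m)")
  p_ <- sweep(dipole_pos, 2L, head$center)
  b <- sqrt(rowSums(p_^2))
  if (any(b >= head$shell_radii[1L] / 1000))
    stop("dipole(s) outside the brain shell")
  re_hat <- e_ / er
  r0_hat <- p_ / ifelse(b > 0, b, 1)
  r0_hat[b == 0, ] <- rep(c(0, 0, 1), each = sum(b == 0))
  x <- b / r3
  qr <- rowSums(dipole_mom * r0_hat)            # n
  q_dot_re <- re_hat %*% t(dipole_mom)          # m x n
  C <- re_hat %*% t(r0_hat)                     # m x n
  C[] <- pmin(1, pmax(-1, C))
  qts <- q_dot_re - sweep(C, 2L, qr, `*`)
  Tn <- three_shell_transfer(head, max_terms)
  m <- nrow(e_); n_src <- nrow(p_)
  V <- matrix(0, m, n_src)
  Pm1 <- matrix(1, m, n_src)    # P_0
  P <- C                        # P_1
  Ppm1 <- matrix(0, m, n_src)   # P'_0
  Pp <- matrix(1, m, n_src)     # P'_1
  xpow <- rep(1, n_src)         # x^(n-1)
  scale <- 1 / (4 * pi * head$conductivities[1L] * r3^2)
  converged <- FALSE
  small_count <- 0L
  for (n in seq_len(max_terms)) {
    term <- Tn[n] * sweep(sweep(P, 2L, n * qr, `*`) + qts * Pp,
                          2L, xpow, `*`)
    V <- V + term
    ref <- max(abs(V))
    if (ref > 0 && max(abs(term)) < tol * ref) {
      small_count <- small_count + 1L
      if (small_count >= 3L) { converged <- TRUE; break }
    } else small_count <- 0L
    if (n == max_terms) break
    # advance recurrences to degree n+1
    Pn1 <- ((2 * n + 1) * C * P - n * Pm1) / (n + 1)
    Ppn1 <- Ppm1 + (2 * n + 1) * P
    Pm1 <- P; P <- Pn1
    Ppm1 <- Pp; Pp <- Ppn1
    xpow <- xpow * x
  }
  if (!converged) {
    achieved <- max(abs(Tn[max_terms] * sweep(sweep(P, 2L, max_terms * qr, `*`)
                                              + qts * Pp, 2L, xpow, `*`))) /
      max(abs(V))
    stop("three-shell series did not converge within ", max_terms,
         " terms (achieved relative tail ", signif(achieved, 3),
         ", requested ", tol, ")")
  }
  scale * V
}

#' Scalp potential of a dipole in a homogeneous sphere (closed form)
#'
#' Closed-form surface potential of a current dipole inside a homogeneous
#' conducting sphere with insulating exterior, obtained by summing the
#' Legendre series with generating functions. Serves as the independent
#' oracle for the multi-shell series when all conductivities are equal.
#'
#' @inheritParams eeg_potential_spheres
#' @param radius sphere radius, mm.
#' @param sigma conductivity, S/m.
#' @param center sphere center, meters.
#' @return m x n matrix of potentials, Volts.
#' @export
potential_homogeneous_sphere <- function(dipole_pos, dipole_mom, electrodes,
                                         radius, sigma = 0.3,
                                         center = c(0, 0, 0)) {
  dipole_pos <- rbind(dipole_pos)
  dipole_mom <- rbind(dipole_mom)
  electrodes <- rbind(electrodes)
  R <- radius / 1000
  e_ <- sweep(electrodes, 2L, center)
  p_ <- sweep(dipole_pos, 2L, center)
  b <- sqrt(rowSums(p_^2))
  re_hat <- e_ / sqrt(rowSums(e_^2))
  r0_hat <- p_ / ifelse(b > 0, b, 1)
  x <- b / R
  qr <- rowSums(dipole_mom * r0_hat)
  Cc <- re_hat %*% t(r0_hat)
  Cc[] <- pmin(1, pmax(-1, Cc))
  qts <- re_hat %*% t(dipole_mom) - sweep(Cc, 2L, qr, `*`)
  X <- matrix(x, nrow(e_), nrow(p_), byrow = TRUE)
  dhat <- sqrt(pmax(0, 1 - 2 * X * Cc + X^2))
  rad_sum <- 2 * X * (Cc - X) / dhat^3 + 1 / dhat - 1
  tan_sum <- 2 * X / dhat^3 + X * (1 + dhat) / (dhat * (1 - X * Cc + dhat))
  V <- (sweep(rad_sum, 2L, qr, `*`) + qts * tan_sum)
  V <- sweep(V, 2L, ifelse(x > 0, x, 1), `/`)
  # dipole at the center: only the n = 1 harmonic survives
  ctr <- x == 0
  if (any(ctr))
    V[, ctr] <- 3 * (re_hat %*% t(dipole_mom[ctr, , drop = FALSE]))
  V / (4 * pi * sigma * R^2)
}
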