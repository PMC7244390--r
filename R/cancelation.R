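#' Physiological scaling constants
#'
#' The current-dipole density of active cortex, `q0` = 1 nAm/mm^2 (stored in
#' SI units as 1e-3 A/m), and the single-dipole moment used for sensitivity
#' maps, 100 nAm. Overriding either value is allowed but logged with a
#' warning, since the downstream signal norms are only physiologically
#' interpretable at the standard values.
#'
#' @param q0 current-dipole density, A/m (SI equivalent of nAm/mm^2).
#' @param sensitivity_moment sensitivity-map dipole moment, A m.
#' @return list with class `cereb_constants`.
#' @export
physiological_constants <- function(q0 = 1e-3, sensitivity_moment = 100e-9) {
  if (abs(q0 - 1e-3) > 1e-9 * 1e-3)
    warning("overriding q0 = 1e-3 A/m (1 nAm/mm^2) with ", q0, " A/m")
  if (abs(sensitivity_moment - 100e-9) > 1e-9 * 100e-9)
    warning("overriding the 100 nAm sensitivity dipole moment with ",
            sensitivity_moment * 1e9, " nAm")
  structure(list(q0 = q0, sensitivity_moment = sensitivity_moment),
            class = "cereb_constants")
}

as_gain_values <- function(G) {
  if (inherits(G, "cereb_gain")) {
    if (length(unique(G$modality)) > 1L)
      stop("gain mixes channel types (", paste(unique(G$modality),
                                               collapse = ", "),
           "); extract one modality with gain_modality() first")
    G$values
  } else as.matrix(G)
}

#' Net and absolute signal of a set of simultaneously active dipoles
#'
#' `net_signal` is the Euclidean norm over channels of the summed forward
#' columns of the active dipoles (all dipoles active simultaneously);
#' `absolute_signal` is the sum of the individual column norms (each dipole
#' active alone). Their ratio is the conservation factor.
#'
#' @param G a single-modality [compute_gain()] result or a plain channels x
#'   sources matrix.
#' @param active integer indices of the active columns.
#' @return scalar signal norm in the modality's channel units.
#' @export
net_signal <- function(G, active) {
  V <- as_gain_values(G)
  if (!length(active)) stop("active set is empty")
  sqrt(sum(rowSums(V[, active, drop = FALSE])^2))
}

#' @rdname net_signal
#' @export
absolute_signal <- function(G, active) {
  V <- as_gain_values(G)
  if (!length(active)) stop("active set is empty")
  sum(sqrt(colSums(V[, active, drop = FALSE]^2)))
}

#' Conservation factor and cancelation index
#'
#' The conservation factor C = A/B relates the net signal A of
#' simultaneously active dipoles to the absolute signal B of the same
#' dipoles activated individually: A = C B. C lies in [0, 1]; C = 1 means
#' no cancelation (net equals absolute), C = 0 complete cancelation. The
#' cancelation index is I_c = 1 - C.
#'
#' @param A net signal norm.
#' @param B absolute signal norm (> 0).
#' @return `conservation_factor`: C; `cancelation_index`: 1 - C.
#' @export
conservation_factor <- function(A, B) {
  if (any(B <= 0))
    stop("absolute signal is zero: conservation factor undefined")
  A / B
}

#' @rdname conservation_factor
#' @param C conservation factor.
#' @export
cancelation_index <- function(C) 1 - C

#' Physiologically scaled signal norms
#'
#' Rescales the unit-dipole norms A and B so that the activated patch
#' carries a current-dipole density of q0 = 1 nAm/mm^2: each of the n
#' dipoles carries moment `a_n * q0 / n`, giving `alpha = A a_n q0 / n` and
#' `beta = B a_n q0 / n`. The ratio alpha/beta equals C, and alpha, beta are
#' invariant to the source-grid density.
#'
#' @param A,B unit-dipole net and absolute signal norms.
#' @param n number of active dipoles (>= 1).
#' @param a_n activated area, m^2 (> 0).
#' @param constants a [physiological_constants()] list.
#' @return list with `alpha` and `beta` in channel units.
#' @export
physiological_norms <- function(A, B, n, a_n,
                                constants = physiological_constants()) {
  stopifnot(all(n >= 1), all(a_n > 0))
  scale <- a_n * constants$q0 / n
  list(alpha = A * scale, beta = B * scale)
}

#' Normalize cerebellar cancelation curves to a cortical reference
#'
#' Forms the cortex-normalized curves: at each patch radius the cerebellar
#' mean of C, beta (and alpha) is divided by the cortical mean at the same
#' radius. The normalized net signal is defined multiplicatively,
#' `alpha_tilde = C_tilde * beta_tilde`, so the identity alpha = C beta
#' carries over to the normalized curves exactly; the direct ratio of mean
#' alphas (which differs by a sampling-covariance factor) is reported
#' alongside as `alpha_tilde_direct`.
#'
#' @param cb,ctx per-sample coherent-patch result tables (from
#'   [run_coherent()]), single surface and modality each.
#' @param radius_grid radii (mm) on which both were evaluated; no
#'   interpolation is performed, grids must match exactly.
#' @return data frame of class `cereb_normalized` with columns `radius_mm`,
#'   `C_tilde`, `beta_tilde`, `alpha_tilde`, `alpha_tilde_direct`, and
#'   per-sample ratio SDs `C_tilde_sd`, `beta_tilde_sd`.
#' @export
normalize_to_reference <- function(cb, ctx, radius_grid) {
  rg_cb <- sort(unique(cb$radius_mm))
  rg_ctx <- sort(unique(ctx$radius_mm))
  radius_grid <- sort(radius_grid)
  if (!isTRUE(all.equal(rg_cb, radius_grid)) ||
      !isTRUE(all.equal(rg_ctx, radius_grid)))
    stop("cerebellar and cortical results must be evaluated on the ",
         "identical radius grid (no interpolation)")
  out <- lapply(radius_grid, function(r) {
    xb <- cb[cb$radius_mm == r, ]
    xc <- ctx[ctx$radius_mm == r, ]
    Cr <- mean(xb$C) / mean(xc$C)
    br <- mean(xb$beta) / mean(xc$beta)
    data.frame(radius_mm = r,
               C_tilde = Cr,
               beta_tilde = br,
               alpha_tilde = Cr * br,
               alpha_tilde_direct = mean(xb$alpha) / mean(xc$alpha),
               C_tilde_sd = stats::sd(xb$C) / mean(xc$C),
               beta_tilde_sd = stats::sd(xb$beta) / mean(xc$beta))
  })
  structure(do.call(rbind, out), class = c("cereb_normalized", "data.frame"))
}
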