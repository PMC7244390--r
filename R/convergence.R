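#' Mesh-convergence study of patch signals under source-grid decimation
#'
#' Quantifies how much sensor-space signals change when the source grid of a
#' finely resolved folded surface is decimated (farthest-point sampling with
#' area reassignment). For each of `n_patches` random coherent patches the
#' patch region is grown once on the full grid; it is then represented (a)
#' at full density and (b) by the decimated vertices owning the region, each
#' vertex carrying its (reassigned) share of the region's area at the
#' standard current-dipole density q0 = 1 nAm/mm^2. Reported per patch and
#' modality are the relative Euclidean difference of the two net signal
#' vectors and the relative differences of the density-scaled net (alpha)
#' and absolute (beta) norms.
#'
#' @param mesh a finely resolved [triangle_mesh()] (edge length well below
#'   the finest fold wavelength).
#' @param sensors a `cereb_sensor_array`.
#' @param engine a [forward_engine()].
#' @param fraction fraction of vertices retained after decimation
#'   (default 0.55).
#' @param n_patches number of random patches (default 20).
#' @param radius_mm nominal patch radius, mm (target area pi r^2).
#' @param seed RNG seed for the patch centers.
#' @param modalities modalities to evaluate.
#' @param constants a [physiological_constants()] list.
#' @return data frame with columns `patch`, `modality`, `signal_diff_pct`,
#'   `alpha_diff_pct`, `beta_diff_pct`, `n_full`, `n_decimated`.
#' @export
mesh_convergence_study <- function(mesh, sensors,
                                   engine = forward_engine(),
                                   fraction = 0.55, n_patches = 20,
                                   radius_mm = 10, seed = 1L,
                                   modalities = "mag",
                                   constants = physiological_constants()) {
  src <- source_space(mesh)
  dec <- decimate_source_space(mesh, max(1L, round(fraction *
                                                     nrow(mesh$vertices))))
  gain <- compute_gain(src, sensors, engine)
  q0 <- constants$q0
  target <- pi * (radius_mm / 1000)^2
  seeds <- with_seed(seed, sample(which(src$kept), n_patches))
  out <- list()
  for (mod in modalities) {
    gm <- gain_modality(gain, mod)
    cn <- sqrt(colSums(gm$values^2))
    for (i in seq_len(n_patches)) {
      patch <- grow_patch(src, seeds[i], target)
      cols_f <- match(patch$vertices, gm$source_index)
      w_f <- src$areas[patch$vertices] * q0
      v_f <- gm$values[, cols_f, drop = FALSE] %*% w_f
      beta_f <- sum(cn[cols_f] * w_f)
      w_by_owner <- rowsum(w_f, dec$owner[patch$vertices])
      own <- as.integer(rownames(w_by_owner))
      cols_d <- match(own, gm$source_index)
      v_d <- gm$values[, cols_d, drop = FALSE] %*% w_by_owner[, 1L]
      beta_d <- sum(cn[cols_d] * w_by_owner[, 1L])
      out[[length(out) + 1L]] <- data.frame(
        patch = i, modality = mod,
        signal_diff_pct = 100 * sqrt(sum((v_f - v_d)^2) / sum(v_f^2)),
        alpha_diff_pct = 100 * abs(sqrt(sum(v_d^2)) - sqrt(sum(v_f^2))) /
          sqrt(sum(v_f^2)),
        beta_diff_pct = 100 * abs(beta_d - beta_f) / beta_f,
        n_full = patch$n, n_decimated = length(own))
    }
  }
  structure(do.call(rbind, out), class = c("cereb_convergence",
                                           "data.frame"))
}
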