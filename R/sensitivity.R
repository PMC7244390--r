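#' Per-vertex sensitivity map
#'
#' For each source vertex, the Euclidean norm of the sensor-space signal of
#' a fixed-moment dipole (default 100 nAm) at that vertex, for one modality.
#' EEG columns are average-referenced before the norm. Vertices excluded by
#' the inner-skull distance rule carry `NA` and are flagged.
#'
#' @param gain a [compute_gain()] result (full, multi-modality allowed).
#' @param modality `"mag"`, `"grad"`, or `"eeg"`.
#' @param moment dipole moment in nAm (default 100).
#' @param n_vertices total vertex count of the underlying source space
#'   (defaults to the maximum source index; excluded vertices are NA).
#' @return An object of class `cereb_sensitivity`: `values` (per-vertex
#'   norms, channel units), `excluded` (logical), `modality`, `moment_nam`.
#' @export
sensitivity_map <- function(gain, modality = c("mag", "grad", "eeg"),
                            moment = 100, n_vertices = NULL) {
  modality <- match.arg(modality)
  gm <- gain_modality(gain, modality)
  norms <- sqrt(colSums(gm$values^2)) * moment * 1e-9
  if (is.null(n_vertices)) n_vertices <- max(gm$source_index)
  values <- rep(NA_real_, n_vertices)
  values[gm$source_index] <- norms
  structure(list(values = values,
                 excluded = is.na(values),
                 modality = modality, moment_nam = moment,
                 units = modality_units(modality)),
            class = "cereb_sensitivity")
}

#' @export
print.cereb_sensitivity <- function(x, ...) {
  ok <- x$values[!x$excluded]
  cat(sprintf(
    "Sensitivity map (%s, %g nAm): %d vertices (%d excluded), median %.3g %s\n",
    x$modality, x$moment_nam, length(x$values), sum(x$excluded),
    stats::median(ok), x$units))
  invisible(x)
}

#' Percentile display range of a sensitivity map
#'
#' Returns the (lo, hi) percentiles of the map values over non-excluded
#' vertices, for color scaling (default 1st to 99th percentile). Percentiles
#' use the linear-interpolation definition (type 7 of [stats::quantile()]).
#'
#' @param map a [sensitivity_map()].
#' @param lo,hi percentiles in [0, 100].
#' @return numeric `c(lo, hi)` in the map's channel units.
#' @export
percentile_clip <- function(map, lo = 1, hi = 99) {
  v <- map$values[!map$excluded]
  if (!length(v)) stop("sensitivity map is empty")
  stats::quantile(v, probs = c(lo, hi) / 100, names = FALSE, type = 7)
}

#' Normalized signal-norm histograms
#'
#' Normalizes single-dipole signal norms of two surfaces to the median of
#' the reference (cortex-like) map and bins them into density-normalized
#' histograms (the integral of each distribution is one). Also reports the
#' medians and the fraction of test-surface vertices whose norm exceeds the
#' reference median.
#'
#' @param map_test,map_ref [sensitivity_map()]s of the same modality
#'   (e.g. cerebellum-like and cortex-like surfaces).
#' @param n_bins number of equal-width bins (default 100) spanning 0 to the
#'   pooled 99.5th percentile.
#' @return list of class `cereb_histogram`: `breaks`, `density_test`,
#'   `density_ref` (normalized norms), `median_test`, `median_ref` (ratio
#'   scale), `exceedance_fraction`.
#' @export
norm_histogram <- function(map_test, map_ref, n_bins = 100) {
  if (map_test$modality != map_ref$modality)
    stop("maps must share a modality (", map_test$modality, " vs ",
         map_ref$modality, ")")
  vt <- map_test$values[!map_test$excluded]
  vr <- map_ref$values[!map_ref$excluded]
  ref_med <- stats::median(vr)
  if (ref_med <= 0) stop("reference median norm is zero")
  xt <- vt / ref_med
  xr <- vr / ref_med
  top <- stats::quantile(c(xt, xr), 0.995, names = FALSE, type = 7)
  breaks <- seq(0, top, length.out = n_bins + 1L)
  ht <- graphics::hist(pmin(xt, top), breaks = breaks, plot = FALSE)
  hr <- graphics::hist(pmin(xr, top), breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks,
                 density_test = ht$density,
                 density_ref = hr$density,
                 median_test = stats::median(xt),
                 median_ref = 1,
                 exceedance_fraction = mean(vt > ref_med),
                 modality = map_test$modality),
            class = "cereb_histogram")
}

#' Export a sensitivity map
#'
#' Writes the per-vertex norms as a CSV sidecar and as the `quality` vertex
#' property of a binary PLY of the source mesh.
#'
#' @param map a [sensitivity_map()].
#' @param mesh the surface mesh the map lives on.
#' @param path_prefix output path without extension.
#' @return invisible vector of written paths.
#' @export
write_sensitivity <- function(map, mesh, path_prefix) {
  p_csv <- paste0(path_prefix, ".csv")
  p_ply <- paste0(path_prefix, ".ply")
  write_vertex_scalar_csv(ifelse(is.na(map$values), -1, map$values), p_csv)
  vals <- map$values
  vals[is.na(vals)] <- -1  # excluded vertices flagged with a negative norm
  write_ply(mesh, p_ply, scalar = vals)
  invisible(c(p_csv, p_ply))
}
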