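#' Forward engine
#'
#' Selects how dipole signals are computed: `sphere_analytic` uses the
#' closed-form magnetic field in a spherically symmetric conductor and the
#' concentric three-shell Legendre series for EEG (fast, exact,
#' deterministic; the default), `bem_collocation` uses the linear-collocation
#' boundary-element method on the head model's boundary meshes (required for
#' non-spherical conductor surrogates).
#'
#' @param method `"sphere_analytic"` or `"bem_collocation"`.
#' @param head a [head_model()]; for the BEM it must carry boundary meshes.
#' @param isolated_skull logical, BEM only: use the isolated-skull approach
#'   (recommended when sigma_skull << sigma_brain).
#' @return An object of class `cereb_forward_engine`.
#' @export
forward_engine <- function(method = c("sphere_analytic", "bem_collocation"),
                           head = head_model(), isolated_skull = TRUE) {
  method <- match.arg(method)
  bem <- NULL
  if (method == "bem_collocation") {
    if (is.null(head$boundary_meshes))
      stop("bem_collocation requires boundary meshes in the head model")
    bem <- bem_model(head, isolated_skull = isolated_skull)
  }
  structure(list(method = method, head = head, bem = bem),
            class = "cereb_forward_engine")
}

#' Compute the gain (lead-field) matrix of a source space
#'
#' One column per kept source vertex, for a unit current dipole (1 A m)
#' along the vertex normal; physiological scaling (`q0`) is applied
#' downstream. Rows follow the sensor array's channel table; EEG rows are
#' stored unreferenced (the average reference is an explicit downstream
#' operator).
#'
#' @param src a [source_space()].
#' @param sensors a `cereb_sensor_array`.
#' @param engine a [forward_engine()].
#' @return An object of class `cereb_gain`: `values` (M x N matrix),
#'   `channels` (channel table), `modality` (per-row: mag/grad/eeg),
#'   `source_index` (kept vertex indices), `source_areas` (m^2).
#' @export
compute_gain <- function(src, sensors, engine = forward_engine()) {
  stopifnot(inherits(src, "cereb_source_space"))
  kept <- which(src$kept)
  if (!length(kept)) stop("source space is empty after exclusion")
  P <- src$positions[kept, , drop = FALSE]
  O <- src$orientations[kept, , drop = FALSE]
  ch <- sensors$channels
  if (engine$method == "bem_collocation") {
    G <- bem_forward(P, O, sensors, engine$bem)
  } else {
    G <- matrix(NA_real_, nrow(ch), nrow(P))
    center <- engine$head$center
    pos <- as.matrix(ch[, c("x", "y", "z")])
    ori <- as.matrix(ch[, c("ox", "oy", "oz")])
    tang <- as.matrix(ch[, c("tx", "ty", "tz")])
    for (r in which(ch$type == "magnetometer"))
      G[r, ] <- sarvas_field_at_point(P, O, pos[r, ], center) %*% ori[r, ]
    for (r in which(ch$type %in% c("gradiometer_x", "gradiometer_y"))) {
      sh <- tang[r, ] * ch$baseline_mm[r] / 2000
      G[r, ] <- (sarvas_field_at_point(P, O, pos[r, ] + sh, center) %*% ori[r, ] -
                   sarvas_field_at_point(P, O, pos[r, ] - sh, center) %*% ori[r, ]) /
        (ch$baseline_mm[r] / 1000)
    }
    el <- which(ch$type == "electrode")
    if (length(el))
      G[el, ] <- eeg_potential_spheres(P, O, pos[el, , drop = FALSE],
                                       engine$head)
  }
  modality <- c(magnetometer = "mag", gradiometer_x = "grad",
                gradiometer_y = "grad", electrode = "eeg")[ch$type]
  structure(list(values = G, channels = ch, modality = unname(modality),
                 source_index = kept, source_areas = src$areas[kept]),
            class = "cereb_gain")
}

#' @export
print.cereb_gain <- function(x, ...) {
  cat(sprintf("Gain matrix: %d channels (%s) x %d sources\n",
              nrow(x$values),
              paste(sprintf("%s: %d", names(table(x$modality)),
                            as.integer(table(x$modality))), collapse = ", "),
              ncol(x$values)))
  invisible(x)
}

#' Subset a gain matrix to a single modality
#'
#' Norm computations never mix channel types (their units differ: T, T/m,
#' V), so the cancelation statistics operate on single-modality gains. EEG
#' columns are average-referenced on extraction by default (the mean over
#' electrodes is subtracted from each column).
#'
#' @param gain a [compute_gain()] result.
#' @param modality `"mag"`, `"grad"`, or `"eeg"`.
#' @param reference apply the average reference to EEG (default TRUE).
#' @return A `cereb_gain` restricted to one modality.
#' @export
gain_modality <- function(gain, modality = c("mag", "grad", "eeg"),
                          reference = TRUE) {
  modality <- match.arg(modality)
  rows <- which(gain$modality == modality)
  if (!length(rows)) stop("gain has no ", modality, " channels")
  vals <- gain$values[rows, , drop = FALSE]
  if (modality == "eeg" && reference) vals <- average_reference(vals)
  structure(list(values = vals, channels = gain$channels[rows, ],
                 modality = gain$modality[rows],
                 source_index = gain$source_index,
                 source_areas = gain$source_areas),
            class = "cereb_gain")
}

#' Average reference operator
#'
#' Subtracts, per column, the mean across channels (electrodes). Constants
#' across electrodes are annihilated.
#'
#' @param values channels x sources matrix.
#' @return re-referenced matrix.
#' @export
average_reference <- function(values) {
  sweep(values, 2L, colMeans(values))
}

#' Persist a gain matrix
#'
#' The numeric block is stored as an RDS file with the channel and source
#' metadata mirrored to CSV next to it.
#'
#' @param gain a `cereb_gain`.
#' @param dir output directory (created if needed).
#' @return `read_gain` returns the `cereb_gain`.
#' @export
write_gain <- function(gain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(gain$values, file.path(dir, "gain_values.rds"))
  utils::write.csv(cbind(gain$channels, modality = gain$modality),
                   file.path(dir, "channels.csv"), row.names = FALSE)
  utils::write.csv(data.frame(column = seq_along(gain$source_index),
                              vertex_index = gain$source_index,
                              area_m2 = gain$source_areas),
                   file.path(dir, "sources.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_gain
#' @export
read_gain <- function(dir) {
  values <- readRDS(file.path(dir, "gain_values.rds"))
  chm <- utils::read.csv(file.path(dir, "channels.csv"))
  srcs <- utils::read.csv(file.path(dir, "sources.csv"))
  structure(list(values = values,
                 channels = chm[, setdiff(names(chm), "modality")],
                 modality = chm$modality,
                 source_index = srcs$vertex_index,
                 source_areas = srcs$area_m2),
            class = "cereb_gain")
}
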