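#' Three-shell spherical head model
#'
#' Piecewise homogeneous conductor with concentric brain, skull, and scalp
#' shells. Default radii 80/85/92 mm and conductivities 0.3/0.006/0.3 S/m.
#'
#' @param shell_radii strictly increasing radii (brain, skull, scalp), mm.
#' @param conductivities conductivities of the brain, skull, and scalp
#'   compartments, S/m.
#' @param center sphere center in meters (default origin).
#' @param boundary_meshes optional list of three closed boundary meshes
#'   (inner skull, outer skull, scalp) for the BEM path.
#' @return An object of class `cereb_head_model`.
#' @export
head_model <- function(shell_radii = c(80, 85, 92),
                       conductivities = c(0.3, 0.006, 0.3),
                       center = c(0, 0, 0),
                       boundary_meshes = NULL) {
  stopifnot(length(shell_radii) == 3L, length(conductivities) == 3L)
  if (any(diff(shell_radii) <= 0))
    stop("shell radii must be strictly increasing (brain < skull < scalp)")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (!is.null(boundary_meshes)) {
    stopifnot(length(boundary_meshes) == 3L)
    lapply(boundary_meshes, function(m) stopifnot(inherits(m, "cereb_mesh")))
  }
  structure(list(shell_radii = shell_radii, conductivities = conductivities,
                 center = center, boundary_meshes = boundary_meshes),
            class = "cereb_head_model")
}

#' @export
print.cereb_head_model <- function(x, ...) {
  cat(sprintf(
    "Head model: shells %s mm, conductivities %s S/m%s\n",
    paste(x$shell_radii, collapse = "/"),
    paste(x$conductivities, collapse = "/"),
    if (is.null(x$boundary_meshes)) "" else " (BEM meshes attached)"))
  invisible(x)
}

# Quasi-uniform points on a spherical cap via a Fibonacci lattice.
# coverage is the polar angle (degrees) from the cap axis down to the rim.
fibonacci_cap <- function(n, coverage, axis = c(0, 0, 1)) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  cz <- 1 - (1 - cos(coverage * pi / 180)) * i / n
  sz <- sqrt(pmax(0, 1 - cz^2))
  ang <- golden * (seq_len(n) - 1)
  pts <- unname(cbind(sz * cos(ang), sz * sin(ang), cz))
  axis <- axis / sqrt(sum(axis^2))
  if (!isTRUE(all.equal(axis, c(0, 0, 1)))) {
    b <- tangent_basis(axis)
    pts <- pts[, 1L] %o% b[1L, ] + pts[, 2L] %o% b[2L, ] + pts[, 3L] %o% axis
  }
  pts
}

#' Synthesize an MEG helmet array
#'
#' Quasi-uniform sensor sites on a spherical cap (Fibonacci lattice). Each
#' site carries one magnetometer oriented along the site's radial direction
#' and two orthogonal planar gradiometers formed as two-point finite
#' differences of the radial field component over the given baseline along
#' the two tangential axes (output units T/m). Channel ordering is
#' site-major: mag, grad_x, grad_y.
#'
#' @param n_sites number of sensor sites (306-channel-style default 102).
#' @param helmet_radius helmet radius, mm; must exceed the scalp radius.
#' @param coverage polar angle of the helmet rim from the +z axis, degrees.
#' @param baseline planar gradiometer baseline, mm (Vectorview-style 16.8).
#' @param scalp_radius scalp radius, mm, used for validation.
#' @return A `cereb_sensor_array`: data frame `channels` with name, type
#'   (`magnetometer`, `gradiometer_x`, `gradiometer_y`), position (meters),
#'   orientation (unit), and baseline (mm; NA for magnetometers).
#' @export
generate_helmet_array <- function(n_sites = 102, helmet_radius = 102,
                                  coverage = 120, baseline = 16.8,
                                  scalp_radius = 92) {
  stopifnot(n_sites >= 4)
  if (helmet_radius <= scalp_radius)
    stop("helmet_radius (", helmet_radius, " mm) must exceed the scalp ",
         "radius (", scalp_radius, " mm)")
  dirs <- fibonacci_cap(n_sites, coverage)
  pos <- dirs * helmet_radius / 1000
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    d <- dirs[s, ]
    tb <- tangent_basis(d)
    rows[[s]] <- data.frame(
      name = sprintf(c("MAG%04d", "GRX%04d", "GRY%04d"), s),
      type = c("magnetometer", "gradiometer_x", "gradiometer_y"),
      x = pos[s, 1L], y = pos[s, 2L], z = pos[s, 3L],
      ox = d[1L], oy = d[2L], oz = d[3L],
      tx = c(NA, tb[1L, 1L], tb[2L, 1L]),
      ty = c(NA, tb[1L, 2L], tb[2L, 2L]),
      tz = c(NA, tb[1L, 3L], tb[2L, 3L]),
      baseline_mm = c(NA, baseline, baseline))
  }
  sensor_array(do.call(rbind, rows))
}

#' Synthesize an EEG electrode cap
#'
#' Quasi-uniform electrode positions on the scalp sphere covering a cap of
#' the given polar angle. Coverage beyond 90 degrees extends the cap below
#' the equator (inferior-posterior electrodes matter for cerebellar EEG
#' sensitivity, so the extension is a parameter rather than a fixed claim).
#'
#' @param n_electrodes number of electrodes (default 72).
#' @param scalp_radius scalp radius, mm.
#' @param coverage polar angle of the lowest electrodes, degrees.
#' @return A `cereb_sensor_array` of `electrode` channels (orientation is
#'   the outward radial direction).
#' @export
generate_electrode_array <- function(n_electrodes = 72, scalp_radius = 92,
                                     coverage = 135) {
  stopifnot(n_electrodes >= 2)
  dirs <- fibonacci_cap(n_electrodes, coverage)
  pos <- dirs * scalp_radius / 1000
  sensor_array(data.frame(
    name = sprintf("EEG%03d", seq_len(n_electrodes)),
    type = "electrode",
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    ox = dirs[, 1L], oy = dirs[, 2L], oz = dirs[, 3L],
    tx = NA_real_, ty = NA_real_, tz = NA_real_,
    baseline_mm = NA_real_))
}

#' Sensor array container
#'
#' @param channels data frame with columns name, type, x, y, z, ox, oy, oz,
#'   tx, ty, tz (tangential gradiometer axis), baseline_mm.
#' @return An object of class `cereb_sensor_array`.
#' @export
sensor_array <- function(channels) {
  needed <- c("name", "type", "x", "y", "z", "ox", "oy", "oz", "baseline_mm")
  if (!all(needed %in% names(channels)))
    stop("channels must contain columns: ", paste(needed, collapse = ", "))
  ok_type <- channels$type %in% c("magnetometer", "gradiometer_x",
                                  "gradiometer_y", "electrode")
  if (!all(ok_type)) stop("unknown channel type(s): ",
                          paste(unique(channels$type[!ok_type]), collapse = ", "))
  onorm <- sqrt(channels$ox^2 + channels$oy^2 + channels$oz^2)
  if (any(abs(onorm - 1) > 1e-9)) stop("orientations must be unit vectors")
  rownames(channels) <- NULL
  structure(list(channels = channels), class = "cereb_sensor_array")
}

#' @export
print.cereb_sensor_array <- function(x, ...) {
  cat("Sensor array:", nrow(x$channels), "channels (",
      paste(sprintf("%s: %d", names(table(x$channels$type)),
                    as.integer(table(x$channels$type))), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Combine sensor arrays
#'
#' @param ... `cereb_sensor_array` objects.
#' @return A single combined `cereb_sensor_array`.
#' @export
combine_arrays <- function(...) {
  sensor_array(do.call(rbind, lapply(list(...), function(a) a$channels)))
}

#' Read/write sensor arrays as CSV
#'
#' Round-trips the channel table (positions in meters, baselines in mm).
#'
#' @param array a `cereb_sensor_array`.
#' @param path CSV file path.
#' @return `read_sensor_csv` returns a `cereb_sensor_array`.
#' @export
write_sensor_csv <- function(array, path) {
  utils::write.csv(array$channels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  sensor_array(utils::read.csv(path))
}

# positions/orientations as plain matrices
sensor_positions <- function(array) {
  as.matrix(array$channels[, c("x", "y", "z")])
}
sensor_orientations <- function(array) {
  as.matrix(array$channels[, c("ox", "oy", "oz")])
}
sensor_tangents <- function(array) {
  as.matrix(array$channels[, c("tx", "ty", "tz")])
}
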