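#' Recipe for a synthetic folded cortical sheet
#'
#' Describes a two-scale sinusoidal height field over a spherical cap. The
#' construction emulates the geometry that drives M/EEG signal cancelation:
#' fine folia-scale folds (1-2 mm wide in the cerebellar cortex) riding on
#' larger lobular folds. The `smoothed-shell` kind keeps only the lobular
#' folds, mimicking an outer-shell segmentation that smooths over the folia.
#' All recipe lengths are in millimeters (the configuration boundary);
#' generated meshes are in meters.
#'
#' @param kind one of `"cerebellum-like"`, `"cortex-like"`,
#'   `"smoothed-shell"`.
#' @param folia_wavelength,folia_amplitude fine-fold wavelength/amplitude, mm.
#' @param lobule_wavelength,lobule_amplitude coarse-fold wavelength/amplitude,
#'   mm.
#' @param cap_center_direction unit 3-vector; direction of the cap center.
#' @param cap_angular_radius angular radius of the cap, degrees.
#' @param base_radius radius of the underlying sphere, mm.
#' @param edge_length target mesh edge length, mm. Must resolve the folia:
#'   `edge_length <= folia_wavelength / 10` whenever `folia_amplitude > 0`.
#' @param seed integer seed fixing the folia phase.
#' @return An object of class `cereb_recipe`.
#' @export
surface_recipe <- function(kind = c("cerebellum-like", "cortex-like",
                                    "smoothed-shell"),
                           folia_wavelength = 2, folia_amplitude = 1,
                           lobule_wavelength = 20, lobule_amplitude = 3,
                           cap_center_direction = c(0, 0, 1),
                           cap_angular_radius = 30,
                           base_radius = 55, edge_length = 0.2,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "smoothed-shell") folia_amplitude <- 0
  if (folia_wavelength <= 0 || lobule_wavelength <= 0)
    stop("wavelengths must be positive")
  if (folia_amplitude > 0 && edge_length > folia_wavelength / 10)
    stop("edge_length = ", edge_length, " mm is too coarse to resolve ",
         "folia of wavelength ", folia_wavelength,
         " mm; need edge_length <= folia_wavelength / 10")
  cap_center_direction <- cap_center_direction / sqrt(sum(cap_center_direction^2))
  structure(list(kind = kind,
                 folia_wavelength = folia_wavelength,
                 folia_amplitude = folia_amplitude,
                 lobule_wavelength = lobule_wavelength,
                 lobule_amplitude = lobule_amplitude,
                 cap_center_direction = cap_center_direction,
                 cap_angular_radius = cap_angular_radius,
                 base_radius = base_radius,
                 edge_length = edge_length,
                 seed = as.integer(seed)),
            class = "cereb_recipe")
}

# Orthonormal tangent basis perpendicular to a unit vector, deterministic.
tangent_basis <- function(d) {
  ref <- if (abs(d[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
          d[3L] * e1[1L] - d[1L] * e1[3L],
          d[1L] * e1[2L] - d[2L] * e1[1L])
  unname(rbind(e1, e2))
}

#' Generate a folded sheet over a spherical cap
#'
#' Builds a height-field surface: points of a regular grid in the cap's
#' tangent coordinates are mapped onto the sphere by the exponential map and
#' displaced radially by
#' `lobule_amplitude * sin(2*pi*s/lobule_wavelength) +
#'  folia_amplitude * sin(2*pi*s/folia_wavelength + phase(seed))`,
#' where `s` is the arc-length coordinate along the first tangential axis.
#' The result is deterministic given the recipe (bit-identical across calls).
#'
#' @param recipe a [surface_recipe()].
#' @param max_radius optional inner-skull radius (mm); the recipe is rejected
#'   when the displaced surface could reach it.
#' @return A [triangle_mesh()] (coordinates in meters).
#' @export
generate_folded_sheet <- function(recipe, max_radius = NULL) {
  stopifnot(inherits(recipe, "cereb_recipe"))
  if (!is.null(max_radius) &&
      recipe$base_radius + recipe$folia_amplitude + recipe$lobule_amplitude >=
        max_radius)
    stop("recipe exceeds the inner-skull radius (", max_radius, " mm): ",
         "base_radius + fold amplitudes must stay strictly inside")
  R <- recipe$base_radius                      # mm, converted at the end
  h <- recipe$edge_length
  s_max <- R * recipe$cap_angular_radius * pi / 180
  phase <- with_seed(recipe$seed, stats::runif(1) * 2 * pi)
  n_half <- ceiling(s_max / h)
  coords <- seq(-n_half, n_half) * h
  grid <- expand.grid(u = coords, v = coords)
  keep <- grid$u^2 + grid$v^2 <= s_max^2
  idx <- matrix(NA_integer_, length(coords), length(coords))
  idx[keep] <- seq_len(sum(keep))
  u <- grid$u[keep]
  v <- grid$v[keep]
  disp <- recipe$lobule_amplitude * sin(2 * pi * u / recipe$lobule_wavelength) +
    recipe$folia_amplitude * sin(2 * pi * u / recipe$folia_wavelength + phase)
  rho <- sqrt(u^2 + v^2)
  psi <- atan2(v, u)
  basis <- tangent_basis(recipe$cap_center_direction)
  dir <- outer(cos(rho / R), recipe$cap_center_direction) +
    sin(rho / R) * (outer(cos(psi), basis[1L, ]) + outer(sin(psi), basis[2L, ]))
  verts <- (R + disp) * dir / 1000             # mm -> m
  # Triangulate grid quads whose four corners are inside the cap.
  nc <- length(coords)
  i <- rep(seq_len(nc - 1L), nc - 1L)
  j <- rep(seq_len(nc - 1L), each = nc - 1L)
  a <- idx[cbind(i, j)]
  b <- idx[cbind(i + 1L, j)]
  c_ <- idx[cbind(i + 1L, j + 1L)]
  d <- idx[cbind(i, j + 1L)]
  ok <- !is.na(a) & !is.na(b) & !is.na(c_) & !is.na(d)
  faces <- rbind(cbind(a[ok], b[ok], c_[ok]), cbind(a[ok], c_[ok], d[ok]))
  # Drop vertices not referenced by any face (isolated rim points).
  used <- sort(unique(as.vector(faces)))
  remap <- integer(length(u))
  remap[used] <- seq_along(used)
  mesh <- triangle_mesh(verts[used, , drop = FALSE],
                        matrix(remap[faces], ncol = 3L))
  # Winding: make normals point along +radial (outward from sphere center).
  fn <- face_normals(mesh)
  ctr <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  if (mean(rowSums(fn * ctr) > 0) < 0.5)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  comp <- igraph::components(mesh_graph(mesh))
  if (comp$no > 1L) {
    keep_v <- comp$membership == which.max(comp$csize)
    keep_f <- keep_v[mesh$faces[, 1L]]
    remap2 <- cumsum(keep_v)
    mesh <- triangle_mesh(mesh$vertices[keep_v, , drop = FALSE],
                          matrix(remap2[mesh$faces[keep_f, ]], ncol = 3L))
  }
  mesh
}

#' Generate an icosphere shell
#'
#' Recursively subdivided icosahedron with all vertices projected onto the
#' sphere of the given radius; used for the brain/skull/scalp boundary
#' meshes of the piecewise-homogeneous conductor model.
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0).
#' @return A closed [triangle_mesh()] with outward normals (meters).
#' @export
generate_sphere_shell <- function(radius, subdivisions = 3L) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  verts <- verts / sqrt(rowSums(verts^2))
  for (s in seq_len(subdivisions)) {
    edge_key <- new.env(hash = TRUE, parent = emptyenv())
    next_vert <- nrow(verts)
    new_rows <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- edge_key[[key]]
      if (!is.null(hit)) return(hit)
      next_vert <<- next_vert + 1L
      m <- verts[i, ] + verts[j, ]
      new_rows[[length(new_rows) + 1L]] <<- m / sqrt(sum(m^2))
      edge_key[[key]] <- next_vert
      next_vert
    }
    new_faces <- matrix(NA_integer_, nrow(faces) * 4L, 3L)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1L]; b <- faces[f, 2L]; c_ <- faces[f, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      new_faces[(4L * f - 3L):(4L * f), ] <-
        rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    verts <- rbind(verts, do.call(rbind, new_rows))
    faces <- new_faces
  }
  orient_outward(triangle_mesh(verts * radius / 1000, faces))
}
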