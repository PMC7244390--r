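#' Triangle surface mesh
#'
#' Container for a triangulated surface. Vertex coordinates are stored in
#' meters (all geometry inside the package is SI; millimeters appear only at
#' the configuration/report boundary). Faces are 1-based integer triples.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in meters.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param validate logical; check invariants (index range, degenerate faces).
#' @return An object of class `cereb_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "cereb_mesh")
  if (validate) {
    if (nrow(faces) == 0L) stop("mesh has no faces")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    fa <- face_areas(mesh)
    if (any(fa <= 0))
      stop("mesh contains ", sum(fa <= 0), " degenerate (zero-area) faces")
  }
  mesh
}

#' @export
print.cereb_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$faces), 1e6 * sum(face_areas(x))))
  invisible(x)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
        e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
        e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
}

#' Per-face areas and unit normals
#'
#' @param mesh a [triangle_mesh()].
#' @return `face_areas`: numeric vector of triangle areas (m^2).
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @return `face_normals`: m x 3 matrix of unit face normals.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  nrm <- sqrt(rowSums(cr^2))
  cr / nrm
}

#' Angle-weighted vertex normals
#'
#' The normal at a vertex is the normalized angle-weighted sum of the unit
#' normals of its incident faces, the weight being the interior angle of the
#' face at that vertex. For closed shells the orientation is made consistently
#' outward (positive signed volume).
#'
#' @param mesh a [triangle_mesh()]. Every vertex must have at least one
#'   incident face.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n_vert <- nrow(v)
  fn <- face_normals(mesh)
  # interior angle of each face corner
  acc <- matrix(0, n_vert, 3L)
  for (k in 1:3) {
    a <- f[, k]
    b <- f[, if (k == 3L) 1L else k + 1L]
    c <- f[, if (k == 1L) 3L else k - 1L]
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    w <- ang * fn
    for (d in 1:3) acc[, d] <- acc[, d] + tabulate_weighted(a, w[, d], n_vert)
  }
  deg <- tabulate(as.vector(f), nbins = n_vert)
  if (any(deg == 0L))
    stop("isolated vertex (no incident face): index ",
         paste(utils::head(which(deg == 0L), 5L), collapse = ", "))
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm == 0))
    stop("zero resultant normal at vertex ", which(nrm == 0)[1L])
  acc / nrm
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Per-vertex areas
#'
#' Each vertex receives one third of the summed areas of its incident faces,
#' so that the vertex areas sum exactly to the total mesh area.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of vertex areas (m^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  n_vert <- nrow(mesh$vertices)
  out <- numeric(n_vert)
  for (k in 1:3)
    out <- out + tabulate_weighted(mesh$faces[, k], fa / 3, n_vert)
  out
}

#' Mesh topology helpers
#'
#' `mesh_edges` returns the unique undirected edges; `mesh_graph` the vertex
#' adjacency as an igraph object (edge weights are Euclidean lengths);
#' `euler_characteristic` the quantity V - E + F (2 for closed shells);
#' `is_closed_mesh` checks that every edge borders exactly two faces;
#' `mesh_volume` the signed enclosed volume via the divergence theorem.
#'
#' @param mesh a [triangle_mesh()].
#' @return See individual descriptions.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

#' @rdname mesh_edges
#' @export
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
                       mesh$vertices[e[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < nrow(mesh$vertices))
    g <- igraph::add_vertices(g, nrow(mesh$vertices) - igraph::vcount(g))
  g
}

#' @rdname mesh_edges
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' @rdname mesh_edges
#' @export
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' @rdname mesh_edges
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
        a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
        a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

# Flip face winding so that a closed shell has outward normals.
orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}
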