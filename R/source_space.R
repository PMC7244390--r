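#' Dipole source space on a triangulated surface
#'
#' Places one fixed-orientation current dipole at every (optionally
#' decimated) mesh vertex, oriented along the angle-weighted vertex normal.
#' Vertex areas (one third of incident face areas, reassigned under
#' decimation) provide the activated-area bookkeeping used by the
#' physiological signal norms. Vertices closer than `min_dist` to the inner
#' skull boundary are flagged as excluded but retained in the container.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_count optional number of source vertices after decimation;
#'   `NULL` keeps every vertex.
#' @param boundary optional inner-skull boundary: a [head_model()], a list
#'   `list(radius = , center = )` (mm / meters respectively) or a closed
#'   [triangle_mesh()].
#' @param min_dist exclusion distance from the boundary, mm (default 5).
#' @return An object of class `cereb_source_space` with elements `positions`
#'   (n x 3, m), `orientations` (unit normals), `areas` (m^2), `kept`
#'   (logical), `graph` (igraph vertex adjacency), `vertex_index` (indices
#'   into the original mesh).
#' @export
source_space <- function(mesh, target_count = NULL, boundary = NULL,
                         min_dist = 5) {
  normals <- vertex_normals(mesh)
  if (is.null(target_count)) {
    positions <- mesh$vertices
    areas <- vertex_areas(mesh)
    graph <- mesh_graph(mesh)
    vidx <- seq_len(nrow(positions))
  } else {
    dec <- decimate_source_space(mesh, target_count)
    vidx <- dec$selected
    positions <- mesh$vertices[vidx, , drop = FALSE]
    areas <- dec$areas
    normals <- normals[vidx, , drop = FALSE]
    graph <- dec$graph
  }
  kept <- if (is.null(boundary)) rep(TRUE, nrow(positions))
          else exclude_near_boundary(positions, boundary, min_dist)
  structure(list(positions = positions, orientations = normals,
                 areas = areas, kept = kept, graph = graph,
                 vertex_index = vidx, mesh = mesh),
            class = "cereb_source_space")
}

#' @export
print.cereb_source_space <- function(x, ...) {
  cat(sprintf(
    "Source space: %d dipoles (%d kept, %d excluded), area %.2f mm^2\n",
    length(x$areas), sum(x$kept), sum(!x$kept), 1e6 * sum(x$areas)))
  invisible(x)
}

#' Decimate a source grid by geodesic farthest-point sampling
#'
#' Selects `target_count` vertices approximately uniformly by geodesic
#' spacing (farthest-point sampling with graph shortest-path distances on
#' the edge graph, starting from vertex 1). The areas of unselected vertices
#' are reassigned to their geodesically nearest selected vertex, so the total
#' represented area is conserved exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_count number of vertices to keep (1..n).
#' @return list with `selected` (vertex indices, in selection order),
#'   `areas` (reassigned areas per selected vertex, m^2), `owner` (for each
#'   original vertex, the selected vertex owning it), and `graph` (contracted
#'   adjacency igraph over the selected vertices).
#' @export
decimate_source_space <- function(mesh, target_count) {
  n <- nrow(mesh$vertices)
  stopifnot(target_count >= 1L, target_count <= n)
  g <- mesh_graph(mesh)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("mesh is disconnected: component sizes ",
         paste(comp$csize, collapse = ", "))
  e <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  res <- fps_sample(n, e, w, as.integer(target_count), 1L)
  sel <- res$selected
  owner <- res$owner
  va <- vertex_areas(mesh)
  areas_by_owner <- rowsum(va, owner)
  pos <- match(sel, as.integer(rownames(areas_by_owner)))
  areas <- as.numeric(areas_by_owner[pos, 1L])
  # Contracted adjacency: selected vertices are adjacent when any original
  # edge crosses their ownership regions.
  oa <- owner[e[, 1L]]
  ob <- owner[e[, 2L]]
  cross <- oa != ob
  rank <- integer(n)
  rank[sel] <- seq_along(sel)
  ce <- unique(cbind(pmin(rank[oa[cross]], rank[ob[cross]]),
                     pmax(rank[oa[cross]], rank[ob[cross]])))
  cg <- igraph::graph_from_edgelist(ce, directed = FALSE)
  if (igraph::vcount(cg) < length(sel))
    cg <- igraph::add_vertices(cg, length(sel) - igraph::vcount(cg))
  igraph::E(cg)$weight <- sqrt(rowSums(
    (mesh$vertices[sel[ce[, 1L]], , drop = FALSE] -
       mesh$vertices[sel[ce[, 2L]], , drop = FALSE])^2))
  list(selected = sel, areas = areas, owner = owner, graph = cg)
}

#' Exclude sources near the inner-skull boundary
#'
#' Returns a keep mask that is `FALSE` for every position closer than
#' `min_dist` to the boundary. For spherical boundaries the distance is the
#' analytic `radius - |p - center|`; for triangulated boundaries the exact
#' point-to-mesh distance is used. Positions outside the boundary raise an
#' error (a source must lie inside the brain compartment).
#'
#' @param positions n x 3 matrix of points, meters.
#' @param boundary a [head_model()], a list `list(radius =, center =)`
#'   (radius mm, center meters), or a closed [triangle_mesh()].
#' @param min_dist minimum allowed distance to the boundary, mm.
#' @return logical keep mask of length n.
#' @export
exclude_near_boundary <- function(positions, boundary, min_dist = 5) {
  positions <- rbind(positions)
  if (inherits(boundary, "cereb_head_model"))
    boundary <- list(radius = boundary$shell_radii[1L], center = boundary$center)
  if (inherits(boundary, "cereb_mesh")) {
    if (!is_closed_mesh(boundary)) stop("boundary mesh is not closed")
    inside <- points_in_closed_mesh(positions, boundary)
    if (any(!inside))
      stop(sum(!inside), " source position(s) lie outside the boundary shell")
    d <- point_mesh_distance(positions, boundary)
    return(d >= min_dist / 1000)
  }
  center <- boundary$center %||% c(0, 0, 0)
  r <- sweep(positions, 2L, center)
  d <- boundary$radius / 1000 - sqrt(rowSums(r^2))
  if (any(d < 0))
    stop(sum(d < 0), " source position(s) lie outside the boundary sphere")
  d >= min_dist / 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact point-to-mesh distance: minimum over per-triangle distances
# (interior projection, clamped edge projections, vertices).
point_mesh_distance <- function(points, mesh) {
  points <- rbind(points)
  np <- nrow(points)
  best <- rep(Inf, np)
  # vertex term
  for (d in seq_len(nrow(mesh$vertices))) {
    dv <- sqrt(rowSums(sweep(points, 2L, mesh$vertices[d, ])^2))
    best <- pmin(best, dv)
  }
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1L], ]; b <- v[f[t, 2L], ]; c_ <- v[f[t, 3L], ]
    n <- fn[t, ]
    pa <- sweep(points, 2L, a)
    hn <- pa %*% n
    proj <- points - hn %*% rbind(n)
    # barycentric test of the projected point
    v0 <- b - a; v1 <- c_ - a
    p0 <- sweep(proj, 2L, a)
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- p0 %*% v0; d21 <- p0 %*% v1
    den <- d00 * d11 - d01 * d01
    bv <- (d11 * d20 - d01 * d21) / den
    bw <- (d00 * d21 - d01 * d20) / den
    inside <- bv >= 0 & bw >= 0 & bv + bw <= 1
    best[inside] <- pmin(best[inside], abs(hn[inside]))
    for (ed in list(list(a, b), list(b, c_), list(c_, a))) {
      ab <- ed[[2L]] - ed[[1L]]
      tt <- pmin(1, pmax(0, sweep(points, 2L, ed[[1L]]) %*% ab / sum(ab^2)))
      q <- sweep(tt %*% rbind(ab), 2L, -ed[[1L]])
      best <- pmin(best, sqrt(rowSums((points - q)^2)))
    }
  }
  best
}

points_in_closed_mesh <- function(points, mesh) {
  # generalized winding number via summed signed triangle solid angles
  total <- numeric(nrow(points))
  v <- mesh$vertices
  f <- mesh$faces
  for (t in seq_len(nrow(f)))
    total <- total + triangle_solid_angle(points, v[f[t, 1L], ],
                                          v[f[t, 2L], ], v[f[t, 3L], ])
  abs(total) > 2 * pi
}

#' Grow a spatially coherent patch around a seed vertex
#'
#' Recursive accretion over the source-space adjacency graph: vertices are
#' added in rings of increasing graph distance from the seed (shortest-path
#' distance with edge lengths, i.e. approximate geodesic distance, so the
#' patch is a geodesic disc), ties within a ring broken by ascending vertex
#' index, until the summed vertex area first reaches `target_area`. Only
#' kept (non-excluded) vertices enter the patch.
#'
#' @param src a [source_space()].
#' @param seed_vertex index of the patch center (must be kept).
#' @param target_area desired patch surface area, m^2. A patch of nominal
#'   radius r corresponds to `target_area = pi * r^2` (flat-disc
#'   equivalent).
#' @param hop_dist optional precomputed graph distances from `seed_vertex`
#'   to every vertex (as from `igraph::distances()`).
#' @return list with `vertices` (included indices), `area` (realized area
#'   a_n, m^2) and `n` (number of dipoles).
#' @export
grow_patch <- function(src, seed_vertex, target_area, hop_dist = NULL) {
  stopifnot(inherits(src, "cereb_source_space"), target_area >= 0)
  if (!src$kept[seed_vertex])
    stop("seed vertex ", seed_vertex, " is excluded from the source space")
  if (is.null(hop_dist))
    hop_dist <- as.numeric(igraph::distances(src$graph, v = seed_vertex))
  cand <- which(src$kept & is.finite(hop_dist))
  ord <- cand[order(hop_dist[cand], cand)]
  cum <- cumsum(src$areas[ord])
  if (cum[length(cum)] < target_area) {
    warning("target_area exceeds total kept surface area; returning all ",
            "kept vertices")
    cut <- length(ord)
  } else {
    cut <- which(cum >= target_area)[1L]
  }
  list(vertices = ord[seq_len(cut)], area = cum[cut], n = cut)
}
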