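#' Read and write surface meshes
#'
#' Meshes are exchanged as binary little-endian PLY or as ASCII OFF. An
#' optional per-vertex scalar channel is carried as the PLY vertex property
#' `quality`, or as a CSV sidecar with columns `vertex_index` (1-based) and
#' `value`. Coordinates are written in meters, as stored.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output/input file path.
#' @param scalar optional numeric per-vertex scalar channel.
#' @return `read_*` return a `cereb_mesh`; if the file carries a scalar it is
#'   attached as attribute `"scalar"`. Writers return `path` invisibly.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_q <- !is.null(scalar)
  if (has_q) stopifnot(length(scalar) == nv)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           "comment cerebsim surface mesh",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           if (has_q) "property double quality",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  vblock <- t(mesh$vertices)
  if (has_q) vblock <- rbind(vblock, as.numeric(scalar))
  writeBin(as.vector(vblock), con, size = 8L, endian = "little")
  f0 <- t(mesh$faces) - 1L
  for (i in seq_len(nf)) {
    writeBin(as.raw(3L), con)
    writeBin(f0[, i], con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  nv <- nf <- NA_integer_
  props <- character()
  in_vertex <- FALSE
  # PLY headers are newline-terminated text in front of a binary body,
  # so the header is consumed byte-wise.
  read_line <- function() {
    out <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  stopifnot(read_line() == "ply")
  fmt <- read_line()
  if (!grepl("binary_little_endian", fmt))
    stop("only binary little-endian PLY is supported")
  repeat {
    line <- read_line()
    if (line == "end_header") break
    tok <- strsplit(line, " +")[[1L]]
    if (tok[1L] == "element" && tok[2L] == "vertex") {
      nv <- as.integer(tok[3L]); in_vertex <- TRUE
    } else if (tok[1L] == "element" && tok[2L] == "face") {
      nf <- as.integer(tok[3L]); in_vertex <- FALSE
    } else if (tok[1L] == "property" && in_vertex && tok[2L] != "list") {
      props <- c(props, tok[3L])
    }
  }
  np <- length(props)
  vdat <- matrix(readBin(con, "double", n = nv * np, size = 8L,
                         endian = "little"), nrow = np)
  verts <- t(vdat[match(c("x", "y", "z"), props), , drop = FALSE])
  scalar <- if ("quality" %in% props) vdat[match("quality", props), ] else NULL
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1L))
    idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
    if (cnt != 3L) stop("non-triangular face in PLY file")
    faces[i, ] <- idx + 1L
  }
  mesh <- triangle_mesh(verts, faces)
  if (!is.null(scalar)) attr(mesh, "scalar") <- scalar
  mesh
}

#' @rdname write_ply
#' @export
write_off <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nv, nf)), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  stopifnot(trimws(lines[1L]) == "OFF")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  fdat <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 ncol = 4L, byrow = TRUE)
  if (any(fdat[, 1L] != 3)) stop("non-triangular face in OFF file")
  triangle_mesh(verts, fdat[, 2:4] + 1L)
}

#' @rdname write_ply
#' @param values per-vertex scalar values for the CSV sidecar.
#' @export
write_vertex_scalar_csv <- function(values, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(values),
                              value = as.numeric(values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_vertex_scalar_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- numeric(max(df$vertex_index))
  out[df$vertex_index] <- df$value
  out
}
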