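test_that("mesh validation catches bad input", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(triangle_mesh(v, rbind(c(1, 2, 3))), "cereb_mesh")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(rbind(v, c(0, 0, 0)),
                             rbind(c(1, 2, 3), c(1, 1, 4))), "degenerate")
})

test_that("vertex areas: closed form, conservation, grid symmetry", {
  # single equilateral triangle, side 1 mm: each vertex gets (sqrt(3)/4)/3
  s <- 1e-3
  v <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  m <- triangle_mesh(v, rbind(c(1, 2, 3)))
  expect_equal(vertex_areas(m), rep(sqrt(3) / 4 * s^2 / 3, 3))
  # conservation on an arbitrary mesh
  m2 <- tiny_sheet()
  expect_lt(abs(sum(vertex_areas(m2)) - sum(face_areas(m2))) /
              sum(face_areas(m2)), 1e-9)
  # uniform planar grid: all interior vertices receive equal area
  g <- expand.grid(x = 0:4, y = 0:4)
  idx <- matrix(seq_len(25), 5, 5)
  f <- NULL
  for (i in 1:4) for (j in 1:4)
    f <- rbind(f, c(idx[i, j], idx[i + 1, j], idx[i + 1, j + 1]),
               c(idx[i, j], idx[i + 1, j + 1], idx[i, j + 1]))
  grid_mesh <- triangle_mesh(cbind(g$x, g$y, 0) * 1e-3, f)
  va <- vertex_areas(grid_mesh)
  interior <- which(g$x %in% 1:3 & g$y %in% 1:3)
  expect_equal(max(va[interior]) / min(va[interior]), 1, tolerance = 1e-12)
  .fixtures$grid_mesh <- grid_mesh
})

test_that("angle-weighted vertex normals are unit, correct, and robust", {
  grid_mesh <- .fixtures$grid_mesh
  n <- vertex_normals(grid_mesh)
  # planar grid: all normals equal the plane normal
  expect_equal(abs(n[, 3]), rep(1, nrow(n)), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(n^2)), rep(1, nrow(n)), tolerance = 1e-12)
  # icosphere: normals radial within 1 degree
  ico <- generate_sphere_shell(80, 2)
  ni <- vertex_normals(ico)
  rad <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  ang <- acos(pmin(1, rowSums(ni * rad))) * 180 / pi
  expect_lt(max(ang), 1)
  # isolated vertex is reported
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(5, 5, 5)), rbind(c(1, 2, 3)))
  expect_error(vertex_normals(bad), "isolated vertex")
})

test_that("icosphere counts, radius, area, and topology", {
  ico0 <- generate_sphere_shell(50, 0)
  expect_equal(nrow(ico0$vertices), 12L)
  expect_equal(nrow(ico0$faces), 20L)
  expect_equal(euler_characteristic(ico0), 2L)
  ico <- generate_sphere_shell(80, 4)
  r <- sqrt(rowSums(ico$vertices^2))
  expect_lt(max(abs(r - 0.08)) / 0.08, 1e-12)
  expect_lt(abs(sum(face_areas(ico)) - 4 * pi * 0.08^2) / (4 * pi * 0.08^2),
            0.005)
  expect_true(is_closed_mesh(ico))
  expect_equal(euler_characteristic(ico), 2L)
  expect_gt(mesh_volume(ico), 0)
})

test_that("PLY and OFF files round-trip, including vertex scalars", {
  m <- tiny_sheet()
  scalar <- seq_len(nrow(m$vertices)) * 1.5
  ply <- tempfile(fileext = ".ply")
  write_ply(m, ply, scalar = scalar)
  m2 <- read_ply(ply)
  expect_equal(m2$vertices, m$vertices)
  expect_equal(m2$faces, m$faces)
  expect_equal(attr(m2, "scalar"), scalar)
  off <- tempfile(fileext = ".off")
  write_off(m, off)
  m3 <- read_off(off)
  expect_equal(m3$vertices, m$vertices, tolerance = 1e-12)
  expect_equal(m3$faces, m$faces)
  csv <- tempfile(fileext = ".csv")
  write_vertex_scalar_csv(scalar, csv)
  expect_equal(read_vertex_scalar_csv(csv), scalar)
})
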