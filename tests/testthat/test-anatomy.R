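test_that("unfolded cap has radial normals and deterministic vertices", {
  m <- flat_cap()
  fn <- face_normals(m)
  ctr <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
  rad <- ctr / sqrt(rowSums(ctr^2))
  ang <- acos(pmin(1, rowSums(fn * rad))) * 180 / pi
  expect_lt(max(ang), 2)  # discretization tolerance of the 2 mm grid
  rec <- surface_recipe("cerebellum-like", cap_angular_radius = 10,
                        edge_length = 0.2, seed = 42)
  m1 <- generate_folded_sheet(rec)
  m2 <- generate_folded_sheet(rec)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
})

test_that("folded area matches the 1-D sinusoid arc-length factor", {
  # folia 1 mm amplitude / 2 mm wavelength (cap size does not enter the
  # 1-D arc-length factor; a 10 mm cap keeps the check fast)
  rec <- surface_recipe("cerebellum-like", folia_wavelength = 2,
                        folia_amplitude = 1, lobule_amplitude = 0,
                        cap_angular_radius = 10 / 55 * 180 / pi,
                        base_radius = 55, edge_length = 0.2, seed = 5)
  flat <- surface_recipe("cerebellum-like", folia_wavelength = 2,
                         folia_amplitude = 0, lobule_amplitude = 0,
                         cap_angular_radius = rec$cap_angular_radius,
                         base_radius = 55, edge_length = 0.2, seed = 5)
  a_folded <- sum(face_areas(generate_folded_sheet(rec)))
  a_flat <- sum(face_areas(generate_folded_sheet(flat)))
  # oracle: numerical quadrature of the arc-length integral of
  # z(s) = A sin(2 pi s / L)
  A <- 1; L <- 2
  f <- function(s) sqrt(1 + (2 * pi * A / L * cos(2 * pi * s / L))^2)
  factor <- stats::integrate(f, 0, L, rel.tol = 1e-10)$value / L
  expect_lt(abs(a_folded / a_flat - factor) / factor, 0.02)
})

test_that("recipes that cannot be realized are rejected", {
  expect_error(surface_recipe("cerebellum-like", folia_wavelength = 2,
                              folia_amplitude = 1, edge_length = 0.5),
               "too coarse")
  expect_error(surface_recipe("cortex-like", folia_wavelength = -1),
               "positive")
  rec <- surface_recipe("cortex-like", folia_amplitude = 0,
                        lobule_amplitude = 15, base_radius = 70,
                        edge_length = 2)
  expect_error(generate_folded_sheet(rec, max_radius = 80), "inner-skull")
})

test_that("smoothed-shell kind drops the folia and loses area", {
  recs <- default_recipes(1)
  expect_equal(recs[["smoothed-shell"]]$folia_amplitude, 0)
  cb <- study_cerebellum()
  sm <- study_smoothed()
  # folding realism: the folia multiply the surface area of the same cap
  expect_gt(sum(face_areas(cb$mesh)), sum(face_areas(sm$mesh)))
})

test_that("generated sheets are connected", {
  m <- tiny_sheet()
  expect_equal(igraph::components(mesh_graph(m))$no, 1L)
})
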