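test_that("helmet array: 306-channel layout, radial magnetometers, spacing", {
  arr <- generate_helmet_array(n_sites = 102, helmet_radius = 102)
  ch <- arr$channels
  expect_equal(nrow(ch), 306L)
  expect_equal(as.vector(table(ch$type)[c("magnetometer", "gradiometer_x",
                                          "gradiometer_y")]),
               c(102L, 102L, 102L))
  # site-major ordering: mag, grad_x, grad_y
  expect_equal(ch$type[1:3],
               c("magnetometer", "gradiometer_x", "gradiometer_y"))
  mags <- ch[ch$type == "magnetometer", ]
  pos <- as.matrix(mags[, c("x", "y", "z")])
  ori <- as.matrix(mags[, c("ox", "oy", "oz")])
  rad <- pos / sqrt(rowSums(pos^2))
  expect_lt(max(abs(ori - rad)), 1e-9)
  # quasi-uniform lattice: min pairwise site distance vs mean NN distance
  dmat <- as.matrix(stats::dist(pos))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, min)
  expect_gt(min(dmat), 0.6 * mean(nn))
  # gradiometer tangents orthogonal to the radial direction
  gx <- ch[ch$type == "gradiometer_x", ]
  tang <- as.matrix(gx[, c("tx", "ty", "tz")])
  expect_lt(max(abs(rowSums(tang * rad))), 1e-9)
  expect_error(generate_helmet_array(helmet_radius = 90, scalp_radius = 92),
               "exceed")
})

test_that("electrode cap: count, on-sphere, and coverage gaps", {
  arr <- generate_electrode_array(n_electrodes = 72, scalp_radius = 92,
                                  coverage = 135)
  ch <- arr$channels
  expect_equal(nrow(ch), 72L)
  pos <- as.matrix(ch[, c("x", "y", "z")])
  expect_lt(max(abs(sqrt(rowSums(pos^2)) - 0.092)) / 0.092, 1e-9)
  # brute-force angular nearest-neighbor gaps over the cap
  u <- pos / 0.092
  cosang <- u %*% t(u)
  diag(cosang) <- -1
  gap <- acos(pmin(1, apply(cosang, 1, max)))
  expect_lt(max(gap), 2.5 * mean(gap))
})

test_that("arrays are deterministic and round-trip through CSV", {
  a1 <- generate_helmet_array(n_sites = 30)
  a2 <- generate_helmet_array(n_sites = 30)
  expect_identical(a1$channels, a2$channels)
  f <- tempfile(fileext = ".csv")
  write_sensor_csv(a1, f)
  a3 <- read_sensor_csv(f)
  expect_equal(a3$channels$x, a1$channels$x, tolerance = 1e-12)
  expect_identical(a3$channels$type, a1$channels$type)
})

test_that("head model validates shells and conductivities", {
  expect_error(head_model(shell_radii = c(85, 80, 92)), "increasing")
  expect_error(head_model(conductivities = c(0.3, 0, 0.3)), "positive")
  hm <- head_model()
  expect_equal(hm$shell_radii, c(80, 85, 92))
  expect_equal(hm$conductivities, c(0.3, 0.006, 0.3))
})
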