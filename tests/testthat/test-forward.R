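test_that("spherical-conductor field: silent sources and the FD oracle", {
  p <- c(0.05, 0.02, 0.01)
  pt <- rbind(c(0.1, 0.05, 0.08))
  # radial dipole is silent
  Br <- meg_field_sphere(rbind(p), rbind(p * 2e-7), pt)
  scale <- max(abs(meg_field_sphere(rbind(p), rbind(c(1e-8, 0, 0)), pt)))
  expect_lt(max(abs(Br)), 1e-15 * scale)
  # dipole at the center is silent
  expect_equal(max(abs(meg_field_sphere(rbind(c(0, 0, 0)),
                                        rbind(c(1e-8, 2e-8, 0)), pt))), 0)
  # tangential dipole vs central-difference gradient of the scalar potential
  r0 <- c(0.03, 0.01, 0.04); Q <- c(1e-8, -2e-8, 5e-9)
  r <- c(0.07, 0.09, 0.06)
  B <- as.numeric(meg_field_sphere(rbind(r0), rbind(Q), rbind(r)))
  expect_rel_equal(B, fd_field_oracle(r, r0, Q), 1e-6)
  # linearity in the moment
  B2 <- as.numeric(meg_field_sphere(rbind(r0), rbind(2 * Q), rbind(r)))
  expect_identical(B2, 2 * B)
  # sensor inside the source radius is rejected
  expect_error(meg_field_sphere(rbind(c(0.07, 0, 0)), rbind(Q),
                                rbind(c(0.05, 0, 0))), "inside")
})

test_that("magnetometer norm decreases as a tangential dipole moves deeper", {
  pt <- rbind(c(0, 0, 0.11))
  depths <- seq(0.07, 0.01, by = -0.01)
  norms <- vapply(depths, function(z)
    sqrt(sum(meg_field_sphere(rbind(c(0, 0, z)), rbind(c(1e-8, 0, 0)),
                              pt)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("three-shell EEG series: oracles and symmetries", {
  el <- cerebsim:::fibonacci_cap(24, 150) * 0.092
  q <- rbind(c(2e-9, -1e-9, 3e-9))
  r0 <- rbind(c(0.01, 0.02, 0.03))
  # equal conductivities reduce to the homogeneous closed form
  hm <- head_model(conductivities = c(0.3, 0.3, 0.3))
  vs <- eeg_potential_spheres(r0, q, el, hm)
  vh <- potential_homogeneous_sphere(r0, q, el, 92, 0.3)
  expect_rel_equal(vs, vh, 1e-6)
  # flipping the dipole negates all potentials exactly
  hm3 <- head_model()
  v1 <- eeg_potential_spheres(r0, q, el, hm3)
  v2 <- eeg_potential_spheres(r0, -q, el, hm3)
  expect_identical(v2, -v1)
  # rigid rotation of dipole + electrodes leaves potentials invariant
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v3 <- eeg_potential_spheres(r0 %*% t(Rz), q %*% t(Rz), el %*% t(Rz), hm3)
  expect_rel_equal(v3, v1, 1e-10)
  # non-convergence is reported with the achieved tolerance
  shallow <- rbind(c(0, 0, 0.0745))
  expect_error(eeg_potential_spheres(shallow, q, el, hm3, max_terms = 10L),
               "did not converge")
  # dipoles outside the brain shell are rejected
  expect_error(eeg_potential_spheres(rbind(c(0, 0, 0.081)), q, el, hm3),
               "outside")
})

test_that("superposition: the signal of a set is the sum of its parts", {
  tg <- tiny_gain()
  G <- gain_modality(tg$gain, "mag")
  set.seed(2)
  act <- sample(ncol(G$values), 17)
  summed <- rowSums(G$values[, act])
  expect_equal(summed,
               Reduce(`+`, lapply(act, function(j) G$values[, j])),
               tolerance = 1e-15)
})
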