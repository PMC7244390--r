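test_that("net and absolute signals match brute-force evaluation", {
  set.seed(3)
  G <- matrix(stats::rnorm(24), 6, 4)
  A <- net_signal(G, 1:4)
  B <- absolute_signal(G, 1:4)
  expect_equal(A, sqrt(sum((G[, 1] + G[, 2] + G[, 3] + G[, 4])^2)))
  expect_equal(B, sum(apply(G, 2, function(c) sqrt(sum(c^2)))))
  # single active dipole: A = B = that column's norm
  expect_equal(net_signal(G, 2), sqrt(sum(G[, 2]^2)))
  expect_equal(net_signal(G, 2), absolute_signal(G, 2))
  # collocated antiparallel pair: B = 2||g||, A = 0
  G2 <- cbind(G[, 1], -G[, 1])
  expect_equal(net_signal(G2, 1:2), 0)
  expect_equal(absolute_signal(G2, 1:2), 2 * sqrt(sum(G[, 1]^2)))
})

test_that("conservation factor limits and the orthogonal-column law", {
  expect_equal(conservation_factor(3, 3), 1)
  expect_equal(conservation_factor(0, 2), 0)
  expect_equal(cancelation_index(0.3), 0.7)
  expect_error(conservation_factor(0, 0), "undefined")
  # n mutually orthogonal equal-norm columns: C = 1/sqrt(n), n = 4
  G <- diag(4) * 2.5
  C <- conservation_factor(net_signal(G, 1:4), absolute_signal(G, 1:4))
  expect_equal(C, 1 / sqrt(4), tolerance = 1e-12)
})

test_that("physiological norms scale correctly and preserve C", {
  # n = 1, a_n = 100 mm^2, A = 1: alpha = 100 mm^2 * 1 nAm/mm^2 = 1e-7 Am
  ph <- physiological_norms(1, 1, 1, 100e-6)
  expect_equal(ph$alpha, 1e-7)
  set.seed(5)
  G <- matrix(stats::rnorm(30), 5, 6)
  A <- net_signal(G, 1:6); B <- absolute_signal(G, 1:6)
  ph2 <- physiological_norms(A, B, 6, 2.3e-4)
  expect_equal(ph2$alpha / ph2$beta, A / B, tolerance = 1e-15)
  expect_warning(physiological_constants(q0 = 2e-3), "overriding")
})

test_that("cortex normalization: identities, homogeneity, grid matching", {
  set.seed(10)
  mk <- function(scale) {
    do.call(rbind, lapply(c(5, 10, 20), function(r) {
      B <- stats::rlnorm(40) * r^2
      C <- stats::runif(40, 0.2, 0.9)
      data.frame(radius_mm = r, C = C, beta = scale * B,
                 alpha = C * scale * B)
    }))
  }
  ctx <- mk(1)
  # self-normalization: all mean ratios are one
  self <- normalize_to_reference(ctx, ctx, c(5, 10, 20))
  expect_equal(self$C_tilde, rep(1, 3), tolerance = 1e-12)
  expect_equal(self$beta_tilde, rep(1, 3), tolerance = 1e-12)
  # halving the gains halves beta_tilde, leaves C_tilde unchanged
  cb <- ctx
  cb$beta <- cb$beta * 0.5
  cb$alpha <- cb$alpha * 0.5
  half <- normalize_to_reference(cb, ctx, c(5, 10, 20))
  expect_equal(half$beta_tilde, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(half$C_tilde, rep(1, 3), tolerance = 1e-12)
  # multiplicative identity holds exactly at every radius
  cb2 <- mk(0.7)
  nc <- normalize_to_reference(cb2, ctx, c(5, 10, 20))
  expect_lt(max(abs(nc$alpha_tilde - nc$C_tilde * nc$beta_tilde)), 1e-12)
  expect_error(normalize_to_reference(cb2, ctx, c(5, 10)), "identical")
})
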