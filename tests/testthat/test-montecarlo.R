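test_that("distributed sampling is uniform, complete, and reproducible", {
  src <- source_space(tiny_sheet())
  N <- sum(src$kept)
  expect_setequal(sample_distributed(src, N), which(src$kept))
  expect_error(sample_distributed(src, N + 1), "exceeds")
  s1 <- with_seed(33, sample_distributed(src, 10))
  s2 <- with_seed(33, sample_distributed(src, 10))
  expect_identical(s1, s2)
  # single-dipole draws hit every vertex uniformly (chi-square over 10,000
  # brute-force counted draws)
  draws <- with_seed(12, replicate(10000, sample_distributed(src, 1)))
  counts <- tabulate(match(draws, which(src$kept)), nbins = N)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-4)
})

test_that("distributed runner reproduces closed-form limits", {
  # synthetic gain of 8 mutually orthogonal equal-norm columns
  G <- structure(list(values = diag(8) * 3,
                      channels = data.frame(type = rep("magnetometer", 8)),
                      modality = rep("mag", 8),
                      source_index = 1:8,
                      source_areas = rep(1e-6, 8)),
                 class = "cereb_gain")
  des <- experiment_design("distributed", n_grid = c(1, 2, 8),
                           samples = 50, seed = 4, modalities = "mag")
  res <- run_distributed(des, list(synthetic = G))
  s <- res$summary
  # n = 1: no cancelation at all
  expect_equal(s$C_mean[s$n == 1], 1, tolerance = 1e-12)
  expect_equal(s$C_sd[s$n == 1], 0, tolerance = 1e-12)
  # orthogonal equal-norm pairs: every sample C = 1/sqrt(2)
  expect_equal(s$C_mean[s$n == 2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(s$C_sd[s$n == 2], 0, tolerance = 1e-12)
  expect_equal(s$C_mean[s$n == 8], 1 / sqrt(8), tolerance = 1e-12)
  # mean C non-increasing in n (the 1/sqrt(n) law)
  expect_true(all(diff(s$C_mean[order(s$n)]) <= 1e-12))
})

test_that("per-sample identities hold on real Monte Carlo output", {
  tg <- tiny_gain()
  des_d <- experiment_design("distributed", n_grid = c(1, 3, 10),
                             samples = 20, seed = 5)
  rd <- run_distributed(des_d, list(tiny = tg$gain))
  des_c <- experiment_design("coherent", radius_grid = c(2, 6),
                             samples = 20, seed = 5)
  rc <- run_coherent(des_c, list(tiny = tg$src), list(tiny = tg$gain))
  for (df in list(rd$samples, rc$samples)) {
    expect_true(all(df$C >= 0 & df$C <= 1 + 1e-12))
    expect_lt(max(abs(df$A - df$C * df$B) / df$B), 1e-12)
    expect_lt(max(abs(df$alpha - df$C * df$beta) /
                    pmax(df$beta, 1e-300)), 1e-12)
  }
})

test_that("coherent runner: single-vertex limit and the flat-sheet limit", {
  # r -> 0: single-vertex patches have C = 1
  tg <- tiny_gain()
  des0 <- experiment_design("coherent", radius_grid = c(0.05),
                            samples = 10, seed = 2)
  r0 <- run_coherent(des0, list(tiny = tg$src), list(tiny = tg$gain))
  expect_true(all(r0$samples$n == 1))
  expect_equal(r0$samples$C, rep(1, nrow(r0$samples)), tolerance = 1e-12)
  # flat unfolded sheet, small patches: aligned normals and a slowly
  # varying lead field keep C near 1
  src <- source_space(flat_cap())
  gain <- compute_gain(src, small_arrays())
  des <- experiment_design("coherent", radius_grid = 3, samples = 30,
                           seed = 3, modalities = c("mag", "eeg"))
  rf <- run_coherent(des, list(flat = src), list(flat = gain))
  expect_gt(min(rf$summary$C_mean), 0.95)
})

test_that("identical design and seed give byte-identical outputs", {
  tg <- tiny_gain()
  des <- experiment_design("coherent", radius_grid = c(3, 6), samples = 15,
                           seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  write_curves(run_coherent(des, list(s = tg$src), list(s = tg$gain)), d1)
  write_curves(run_coherent(des, list(s = tg$src), list(s = tg$gain)), d2)
  f1 <- file.path(d1, "coherent_samples.csv")
  f2 <- file.path(d2, "coherent_samples.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("patches that exhaust the surface are retained and counted", {
  tg <- tiny_gain()
  des <- experiment_design("coherent", radius_grid = 50, samples = 5,
                           seed = 1, modalities = "mag")
  res <- run_coherent(des, list(s = tg$src), list(s = tg$gain))
  expect_equal(attr(res, "n_saturated"), 5L)
  expect_equal(unique(res$samples$n), sum(tg$src$kept))
})
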