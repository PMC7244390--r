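test_that("sensitivity maps are linear and match direct forward calls", {
  tg <- tiny_gain()
  m1 <- sensitivity_map(tg$gain, "mag", moment = 100)
  m2 <- sensitivity_map(tg$gain, "mag", moment = 200)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-15)
  # brute-force recomputation at 10 random vertices
  src <- tg$src
  ch <- tg$gain$channels
  mag_rows <- which(ch$type == "magnetometer")
  pos <- as.matrix(ch[mag_rows, c("x", "y", "z")])
  ori <- as.matrix(ch[mag_rows, c("ox", "oy", "oz")])
  set.seed(21)
  for (j in sample(which(!m1$excluded), 10)) {
    b <- vapply(seq_len(nrow(pos)), function(r)
      sum(meg_field_sphere(rbind(src$positions[j, ]),
                           rbind(src$orientations[j, ] * 100e-9),
                           rbind(pos[r, ])) * ori[r, ]), numeric(1))
    expect_equal(m1$values[j], sqrt(sum(b^2)), tolerance = 1e-12)
  }
})

test_that("EEG maps are reference-invariant to common offsets", {
  tg <- tiny_gain()
  g2 <- tg$gain
  el <- g2$modality == "eeg"
  g2$values[el, ] <- g2$values[el, ] + 3.14
  expect_equal(sensitivity_map(g2, "eeg")$values,
               sensitivity_map(tg$gain, "eeg")$values, tolerance = 1e-9)
})

test_that("percentile clipping uses linear-interpolation percentiles", {
  const_map <- structure(list(values = rep(2.5, 50), excluded = rep(FALSE, 50)),
                         class = "cereb_sensitivity")
  expect_equal(percentile_clip(const_map), c(2.5, 2.5))
  seq_map <- structure(list(values = as.numeric(0:100),
                            excluded = rep(FALSE, 101)),
                       class = "cereb_sensitivity")
  expect_equal(percentile_clip(seq_map), c(1, 99))
  set.seed(13)
  v <- stats::rlnorm(500)
  rmap <- structure(list(values = v, excluded = rep(FALSE, 500)),
                    class = "cereb_sensitivity")
  # sorting oracle for the type-7 definition
  sv <- sort(v)
  h <- (500 - 1) * 0.01 + 1
  lo_oracle <- sv[floor(h)] + (h - floor(h)) * (sv[floor(h) + 1] - sv[floor(h)])
  expect_equal(percentile_clip(rmap)[1], lo_oracle, tolerance = 1e-12)
})

test_that("norm histograms are density-normalized with exact exceedance", {
  tg <- tiny_gain()
  m <- sensitivity_map(tg$gain, "mag")
  h_self <- norm_histogram(m, m)
  expect_equal(h_self$median_test, 1, tolerance = 1e-12)
  expect_lt(abs(sum(h_self$density_test * diff(h_self$breaks)) - 1), 1e-9)
  expect_lt(abs(sum(h_self$density_ref * diff(h_self$breaks)) - 1), 1e-9)
  # exceedance equals brute-force counting
  m2 <- sensitivity_map(tg$gain, "eeg")
  expect_error(norm_histogram(m, m2), "modality")
  half <- m
  half$values <- half$values * 0.8
  h <- norm_histogram(half, m)
  med <- stats::median(m$values[!m$excluded])
  expect_equal(h$exceedance_fraction,
               sum(half$values[!half$excluded] > med) /
                 sum(!half$excluded))
})

test_that("deeper cerebellum-like sources are less visible in every modality", {
  cb <- study_cerebellum(); ctx <- study_cortex()
  for (mod in c("mag", "grad", "eeg")) {
    mcb <- sensitivity_map(cb$gain, mod)
    mctx <- sensitivity_map(ctx$gain, mod)
    expect_lt(mean(mcb$values, na.rm = TRUE),
              mean(mctx$values, na.rm = TRUE))
  }
})

test_that("near-radial sources are magnetically silent in the map", {
  ctx <- study_cortex()
  src <- ctx$src
  m <- sensitivity_map(ctx$gain, "mag")
  radial <- src$positions / sqrt(rowSums(src$positions^2))
  ang <- acos(pmin(1, abs(rowSums(src$orientations * radial)))) * 180 / pi
  sel <- which(ang < 2 & !m$excluded)
  expect_gt(length(sel), 0)
  expect_lt(max(m$values[sel]), 0.1 * percentile_clip(m)[2])
})
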