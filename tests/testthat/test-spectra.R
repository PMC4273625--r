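test_that("identical and sign-flipped signals are perfectly coherent", {
  set.seed(1)
  x <- rnorm(400)
  panel <- ts_panel(cbind(a = x, b = x, c = -x), dt = 1)
  sp <- coherence_spectrum(panel, spectral_settings(segment_length = 64))
  expect_true(all(abs(sp$values[1, 2, ] - 1) < 1e-10))
  expect_true(all(abs(sp$values[1, 3, ] - 1) < 1e-10))
})

test_that("independent white noise matches the Monte-Carlo no-coupling bias", {
  settings <- spectral_settings()
  # oracle: distribution of the frequency-averaged coherence of independent
  # 610-sample pairs under the default spectral settings
  set.seed(99)
  oracle <- replicate(300, {
    p <- ts_panel(matrix(rnorm(610 * 2), 610, 2), dt = 2)
    mean(coherence_spectrum(p, settings)$values[1, 2, ])
  })
  set.seed(12345)
  test_pair <- ts_panel(matrix(rnorm(610 * 2), 610, 2), dt = 2)
  observed <- mean(coherence_spectrum(test_pair, settings)$values[1, 2, ])
  expect_lt(abs(observed - mean(oracle)), 3 * sd(oracle))
  # the bias is small but positive
  expect_gt(mean(oracle), 0)
  expect_lt(mean(oracle), 0.3)
})

test_that("band ladder construction matches the 23-band analysis grid", {
  bands <- make_bands(0.01, 0.25, 0.02, 0.5)
  expect_length(bands, 23L)
  expect_equal(vapply(bands, function(b) b$center, numeric(1)),
               seq(0.02, 0.24, by = 0.01))
  expect_length(make_bands(0.01, 0.03, 0.02, 0.5), 1L)
  two <- make_bands(0.01, 0.05, 0.02, 0)
  expect_length(two, 2L)
  expect_equal(two[[2]]$lo, two[[1]]$hi)
  expect_error(make_bands(0.05, 0.01, 0.02, 0.5), "invalid")
  expect_error(make_bands(0.01, 0.25, 0.02, 1), "invalid")
})

make_spectrum <- function(values, freqs) {
  structure(list(values = values, freqs = freqs,
                 settings = spectral_settings(), dt = 1),
            class = "coh_spectrum")
}

test_that("band averaging reduces the spectrum as an entrywise mean", {
  freqs <- seq(0.01, 0.1, by = 0.01)
  const <- array(0.4, dim = c(3, 3, length(freqs)))
  sp <- make_spectrum(const, freqs)
  cm <- band_average(sp, band(0.02, 0.06))
  expect_true(all(cm$values[upper.tri(cm$values)] == 0.4))
  expect_true(all(diag(cm$values) == 1))

  # full-grid band equals the direct mean over all frequencies
  set.seed(3)
  vals <- array(runif(3 * 3 * 10), dim = c(3, 3, 10))
  for (k in 1:10) {
    vals[, , k][lower.tri(vals[, , k])] <- t(vals[, , k])[lower.tri(vals[, , k])]
  }
  spr <- make_spectrum(vals, freqs)
  full <- band_average(spr, band(0.005, 0.2, closed_upper = TRUE))
  expect_equal(full$values[1, 2], mean(vals[1, 2, ]))

  # two in-band grid points at 0.2 and 0.4 average to 0.3
  v2 <- array(1, dim = c(2, 2, 4))
  v2[1, 2, ] <- v2[2, 1, ] <- c(0.9, 0.2, 0.4, 0.9)
  sp2 <- make_spectrum(v2, c(0.01, 0.02, 0.03, 0.04))
  expect_equal(band_average(sp2, band(0.015, 0.035))$values[1, 2], 0.3)

  expect_error(band_average(sp2, band(0.2, 0.22)), "no frequency-grid")
})

test_that("system curves equal hand-enumerated pair means", {
  freqs <- c(0.02, 0.04)
  v <- array(1, dim = c(3, 3, 2))
  v[1, 2, ] <- v[2, 1, ] <- c(0.6, 0.4)   # pair within system X
  v[1, 3, ] <- v[3, 1, ] <- c(0.3, 0.1)   # across systems
  v[2, 3, ] <- v[3, 2, ] <- c(0.5, 0.3)   # across systems
  sp <- make_spectrum(v, freqs)
  tab <- data.frame(system = c("X", "X", "Y"))
  sc <- system_curves(sp, tab, list(band(0.015, 0.045, closed_upper = TRUE)))
  expect_equal(sc$intra, 0.5)               # mean(0.6, 0.4)
  expect_equal(sc$inter, mean(c(0.3, 0.1, 0.5, 0.3)))

  one <- system_curves(sp, data.frame(system = c("X", "X", "X")),
                       list(band(0.015, 0.045, closed_upper = TRUE)))
  expect_true(is.na(one$inter))
})

test_that("planted band coupling peaks both curves at 0.02 and 0.08 Hz", {
  sc <- small_cohort(3)
  roi <- load_roi_table()
  bands <- make_bands()
  curves <- lapply(sc$panels, function(p) {
    system_curves(coherence_spectrum(p), roi, bands)
  })
  intra <- rowMeans(sapply(curves, `[[`, "intra"))
  inter <- rowMeans(sapply(curves, `[[`, "inter"))
  centers <- curves[[1]]$center
  expect_setequal(round(centers[order(-intra)][1:2], 6), c(0.02, 0.08))
  expect_setequal(round(centers[order(-inter)][1:2], 6), c(0.02, 0.08))
})

test_that("coherence stays within [0, 1] and permutes with ROI relabeling", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(60:120, 1)
    p <- sample(3:5, 1)
    vals <- matrix(rnorm(n * p), n, p)
    if (i %% 3 == 0) vals <- vals^3  # heavy-tailed
    panel <- ts_panel(vals, dt = 1)
    sp <- coherence_spectrum(panel, spectral_settings(segment_length = 32))
    expect_true(all(sp$values >= 0 & sp$values <= 1 + 1e-12))
    expect_equal(sp$values[1, 2, ], sp$values[2, 1, ])
  }
  # relabeling ROIs permutes the coherence array consistently
  set.seed(12)
  vals <- matrix(rnorm(300 * 4), 300, 4)
  perm <- c(3, 1, 4, 2)
  s1 <- coherence_spectrum(ts_panel(vals, dt = 1),
                           spectral_settings(segment_length = 64))
  s2 <- coherence_spectrum(ts_panel(vals[, perm], dt = 1),
                           spectral_settings(segment_length = 64))
  expect_equal(s2$values, s1$values[perm, perm, ], tolerance = 1e-12)
})

test_that("in-band coupling raises band-averaged coherence above out-of-band", {
  hits <- 0L
  for (r in 1:30) {
    cfg <- generator_config(n_rois = 4, n_subjects = 1,
                            bands = list(b = list(lo = 0.05, hi = 0.07,
                                                  alpha = 0.7, beta = 0)),
                            hub_rois = integer(), subject_sd = 0,
                            planted_partition = rep(1L, 4),
                            seed = 5000L + r)
    sp <- coherence_spectrum(generate_cohort(cfg)[[1]])
    inband <- band_average(sp, band(0.05, 0.07))$values[1, 2]
    outband <- band_average(sp, band(0.15, 0.17))$values[1, 2]
    hits <- hits + (inband > outband)
  }
  expect_gte(hits / 30, 0.95)
})
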