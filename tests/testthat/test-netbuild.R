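test_that("sparsity thresholding realizes the exact edge count", {
  set.seed(5)
  m <- matrix(runif(87^2), 87, 87)
  cm <- (m + t(m)) / 2
  a <- sparsity_threshold(cm, 0.25)
  expect_equal(sum(a$values) / 2, 935)  # floor(0.25 * 87 * 86 / 2)
  expect_true(isSymmetric(a$values))
  expect_true(all(diag(a$values) == 0))

  full <- sparsity_threshold(cm, 1)
  expect_equal(sum(full$values) / 2, 87 * 86 / 2)

  # hand-ranked 4-node example: S = 0.5 keeps the 3 strongest of 6 pairs
  v <- matrix(0, 4, 4)
  v[1, 2] <- 0.9; v[1, 3] <- 0.8; v[1, 4] <- 0.7
  v[2, 3] <- 0.1; v[2, 4] <- 0.1; v[3, 4] <- 0.1
  v <- v + t(v)
  a3 <- sparsity_threshold(v, 0.5)
  expect_equal(which(a3$values[upper.tri(a3$values)] == 1), c(1L, 2L, 4L))

  expect_error(sparsity_threshold(v, 0.01), "retains no edges")
  expect_error(sparsity_threshold(v, 0), "\\(0, 1\\]")
})

test_that("thresholding is monotone in S with the deterministic tie-break", {
  set.seed(6)
  for (r in 1:25) {
    n <- sample(10:30, 1)
    m <- matrix(runif(n^2), n, n)
    cm <- (m + t(m)) / 2
    if (r %% 5 == 0) cm[] <- round(cm, 1)  # force ties
    ss <- sort(runif(2, 0.1, 0.9))
    a1 <- sparsity_threshold(cm, ss[1])$values
    a2 <- sparsity_threshold(cm, ss[2])$values
    expect_true(all(a2[a1 == 1] == 1))  # edge set at S1 subset of S2
    n_pairs <- n * (n - 1) / 2
    expect_equal(sum(a1) / 2, floor(ss[1] * n_pairs))
  }
  # uniform matrix: pure tie-break, repeated runs identical and lexicographic
  u <- matrix(0.5, 6, 6); diag(u) <- 0
  b1 <- sparsity_threshold(u, 0.3)$values
  b2 <- sparsity_threshold(u, 0.3)$values
  expect_identical(b1, b2)
  # lexicographic (i, j) tie-break keeps pairs (1,2) (1,3) (1,4) (1,5)
  expect_equal(which(b1[1, ] == 1), 2:5)
  expect_equal(sum(b1) / 2, 4)
})

test_that("consistent edge matrices average adjacency across subjects", {
  set.seed(7)
  m <- matrix(runif(100), 10, 10)
  cm <- structure(list(values = (m + t(m)) / 2, band = band(0.01, 0.03)),
                  class = "coh_matrix")
  a <- sparsity_threshold(cm, 0.3)
  ce_same <- consistency_matrix(list(a, a, a))
  expect_identical(ce_same$values, a$values + 0)

  b <- a
  b$values <- 1L - a$values
  diag(b$values) <- 0L
  ce_comp <- consistency_matrix(list(a, b))
  off <- ce_comp$values[upper.tri(ce_comp$values)]
  expect_true(all(off == 0.5))
  expect_true(all(ce_comp$values >= 0 & ce_comp$values <= 1))

  mixed <- a
  mixed$band <- band(0.07, 0.09)
  expect_error(consistency_matrix(list(a, mixed)), "mixed bands")
})

test_that("group networks reproduce shared structure and flag disconnection", {
  set.seed(8)
  m <- matrix(runif(144), 12, 12)
  cm <- structure(list(values = (m + t(m)) / 2, band = band(0.01, 0.03)),
                  class = "coh_matrix")
  a <- sparsity_threshold(cm, 0.4)
  g <- group_network(consistency_matrix(list(a, a)), 0.4)
  expect_identical(g$adjacency$values, a$values)
  expect_equal(g$connected,
               igraph::is_connected(igraph::graph_from_adjacency_matrix(
                 a$values, mode = "undirected")))

  # structurally isolated node at small S
  ce <- matrix(0.9, 8, 8)
  ce[8, ] <- ce[, 8] <- 0.01
  diag(ce) <- 0
  iso <- group_network(structure(list(values = ce, kind = "edge", band = NULL),
                                 class = "consistency"), 0.3)
  expect_false(iso$connected)
})

test_that("surrogate nulls break alignment and are calibrated", {
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.6), 610))
  panel <- ts_panel(cbind(a = x, b = x + rnorm(610, sd = 1e-6)), dt = 2)
  bd <- band(0.05, 0.07)
  nl <- coherence_null(panel, c(1, 2), bd, n_boot = 200, seed = 2)
  expect_equal(nl$observed, 1, tolerance = 1e-6)
  expect_lt(mean(nl$values), 0.5)      # surrogates destroy the alignment
  expect_lt(nl$critical, nl$observed)

  np <- coherence_null(panel, c(1, 2), bd, n_boot = 100, seed = 2,
                       method = "phase")
  expect_lt(mean(np$values), 0.5)
  expect_error(coherence_null(panel, c(1, 2), bd, n_boot = 10), "at least 100")

  # coverage: for independent white noise the observed coherence exceeds the
  # 95% null quantile about 5% of the time (scaled-down Monte Carlo)
  set.seed(10)
  rejections <- replicate(150, {
    p <- ts_panel(matrix(rnorm(610 * 2), 610, 2), dt = 2)
    nn <- coherence_null(p, c(1, 2), bd, n_boot = 119,
                         seed = sample.int(2^30, 1))
    nn$observed > nn$critical
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.045)
})

test_that("sparsity floor selection admits only null-beating thresholds", {
  # hand-built subjects: coherence values known exactly
  mk <- function(vals) {
    v <- matrix(0, 4, 4)
    v[upper.tri(v)] <- vals
    v <- v + t(v); diag(v) <- 1
    structure(list(values = v, band = band(0.01, 0.03)), class = "coh_matrix")
  }
  s1 <- mk(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  s2 <- mk(c(0.95, 0.85, 0.75, 0.65, 0.55, 0.45))
  # grid S: 1/6, 2/6, ..., edges m = 1..5; cutoffs are the m-th largest
  grid <- c(1, 2, 3, 4, 5) / 6
  fl <- validate_sparsity_floor(list(s1, s2), grid, nulls = 0.55)
  # admissible while the weakest retained coherence of BOTH subjects > 0.55:
  # subject 1 cutoffs 0.9 0.8 0.7 0.6 0.5 -> fails at m = 5
  expect_equal(fl$selected, 4 / 6)
  expect_equal(unname(fl$admissible), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  one <- validate_sparsity_floor(list(s1, s2), 2 / 6, nulls = 0.55)
  expect_equal(one$selected, 2 / 6)
  expect_error(validate_sparsity_floor(list(s1, s2), grid, nulls = 0.99),
               "no sparsity")
})

test_that("the full grid up to S = 0.25 is significant on a coupled cohort", {
  sc <- small_cohort(4)
  vlf <- band(0.01, 0.03)
  mats <- lapply(sc$panels, function(p) {
    band_average(coherence_spectrum(p), vlf)
  })
  set.seed(21)
  noise <- ts_panel(matrix(rnorm(610 * 2), 610, 2), dt = 2)
  nl <- coherence_null(noise, c(1, 2), vlf, n_boot = 300, seed = 5)
  fl <- validate_sparsity_floor(mats, seq(0.05, 0.25, by = 0.05),
                                nulls = nl$critical)
  expect_equal(fl$selected, 0.25)
  expect_true(all(fl$admissible))
})
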