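test_that("modularity matches hand-derived closed forms", {
  tt <- twin_triangles()
  expect_equal(modularity_q(tt, rep(1L, 6)), 0)           # e_11 = 1
  expect_equal(modularity_q(tt, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_lt(modularity_q(tt, c(1, 1, 3, 2, 2, 2)), 0.5)   # split one triangle
  expect_error(modularity_q(matrix(0L, 4, 4), rep(1L, 4)), "edgeless")
})

test_that("modularity agrees with the igraph reference implementation", {
  set.seed(13)
  for (r in 1:25) {
    a <- random_graph(sample(6:15, 1), 0.4)
    if (sum(a) == 0) next
    labels <- sample(1:3, nrow(a), replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(modularity_q(a, labels), igraph::modularity(g, labels),
                 tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted cliques and is seeded-deterministic", {
  a <- matrix(0L, 10, 10)
  a[1:5, 1:5] <- 1L; a[6:10, 6:10] <- 1L; diag(a) <- 0L
  p <- louvain_partition(a, n_restarts = 10, seed = 1)
  expect_equal(p$n_communities, 2L)
  expect_equal(p$modularity_q, 0.5)
  expect_length(unique(p$labels[1:5]), 1L)
  expect_length(unique(p$labels[6:10]), 1L)

  k6 <- complete_graph(6)
  pk <- louvain_partition(k6, n_restarts = 10, seed = 1)
  expect_equal(pk$n_communities, 1L)
  expect_equal(pk$modularity_q, 0)

  set.seed(77)
  w <- matrix(runif(400), 20, 20); w <- (w + t(w)) / 2; diag(w) <- 0
  expect_identical(louvain_partition(w, n_restarts = 5, seed = 9)$labels,
                   louvain_partition(w, n_restarts = 5, seed = 9)$labels)
  expect_error(louvain_partition(matrix(0, 4, 4)), "all-zero")
})

test_that("consensus assignment averages co-assignment indicators", {
  parts <- list(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 2, 2))
  cons <- consensus_assignment(parts, n_restarts = 5, seed = 1)
  expect_true(all(cons$ca$values %in% c(0, 1)))
  expect_equal(nmi(cons$partition, parts[[1]]), 1)

  orth <- consensus_assignment(list(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                               n_restarts = 5, seed = 1)
  off <- orth$ca$values[upper.tri(orth$ca$values)]
  # pairs (1,2), (3,4), (1,3), (2,4) are co-assigned by one of the two
  # subjects; pairs (1,4) and (2,3) by neither
  expect_equal(sort(off), c(0, 0, 0.5, 0.5, 0.5, 0.5))
  expect_true(all(orth$ca$values >= 0 & orth$ca$values <= 1))
  expect_error(consensus_assignment(list(c(1, 1, 2), c(1, 2))), "different")
})

test_that("NMI matches the printed formula on reference cases", {
  set.seed(14)
  for (r in 1:10) {
    p <- sample(1:4, 50, replace = TRUE)
    expect_equal(nmi(p, p), 1)
  }
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # degenerate single-community cases
  expect_equal(nmi(rep(1, 8), rep(1, 8)), 1)
  expect_equal(nmi(rep(1, 8), rep(1:2, 4)), 0)
  # published values for the packaged parcellation
  roi <- load_roi_table()
  expect_equal(round(nmi(roi$community_vlf, roi$community_lf), 2), 0.59)
  expect_equal(round(nmi(roi$community_vlf, roi$system), 2), 0.33)
  expect_equal(round(nmi(roi$community_lf, roi$system), 2), 0.32)
})

test_that("NMI is symmetric and relabeling-invariant", {
  set.seed(15)
  for (r in 1:200) {
    n <- sample(5:40, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    v <- nmi(a, b)
    expect_equal(v, nmi(b, a), tolerance = 1e-12)
    relab <- c(9, 2, 7, 5)[a]  # arbitrary renaming of community ids
    expect_equal(nmi(relab, b), v, tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("partition similarity of coupled networks beats randomized nulls", {
  # two noisy realizations of the same 3-block structure
  blocks <- rep(1:3, each = 10)
  sbm <- function(seed) {
    set.seed(seed)
    p <- ifelse(outer(blocks, blocks, "=="), 0.75, 0.05)
    a <- matrix(0L, 30, 30)
    ut <- upper.tri(a)
    a[ut] <- as.integer(runif(sum(ut)) < p[ut])
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
    structure(list(values = a, band = NULL, sparsity = NA), class = "adjacency")
  }
  res <- nmi_significance(sbm(1), sbm(2), n_null = 1000, seed = 3,
                          n_restarts = 20)
  expect_gt(res$nmi, 0.8)
  expect_lte(res$p_value, 0.001)

  # external reference partition: both null families are reported
  ext <- nmi_significance(sbm(1), blocks, n_null = 150, seed = 4,
                          n_restarts = 10)
  expect_gt(ext$nmi, 0.8)
  expect_lte(ext$p_value, 0.01)
  expect_length(ext$null_rewired, 150)
  expect_length(ext$null_random, 150)
  expect_gte(ext$p_value, max(ext$p_rewired, ext$p_random) - 1e-12)
})

test_that("independent density-matched graphs are usually not similar", {
  ps <- vapply(1:11, function(s) {
    set.seed(100 + s)
    g1 <- igraph::as_adjacency_matrix(igraph::sample_gnm(40, 120), sparse = FALSE)
    g2 <- igraph::as_adjacency_matrix(igraph::sample_gnm(40, 120), sparse = FALSE)
    nmi_significance(g1, g2, n_null = 100, seed = 200 + s,
                     n_restarts = 5)$p_value
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)
})
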