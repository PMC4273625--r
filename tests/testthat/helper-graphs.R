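# Small graph constructors and brute-force oracles shared across tests.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

# two disjoint triangles on 6 nodes
twin_triangles <- function() {
  adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
}

star_graph <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- 1L
  a[2:n, 1] <- 1L
  a
}

random_graph <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.integer(runif(sum(ut)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# All set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (lab in seq_len(maxlab + 1L)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(), 0L)
  out
}

# Brute-force modularity optimum by exhaustive enumeration of partitions
brute_modularity_opt <- function(a, parts = all_partitions(nrow(a))) {
  max(vapply(parts, function(p) modularity_q(a, p), numeric(1)))
}

# Brute-force Benjamini-Yekutieli step-up (the definition, independent of
# p.adjust): reject the r smallest p-values for the largest rank r with
# p_(r) <= r q / (m c(m))
brute_by <- function(p, q = 0.05) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / (m * cm))
  flags <- rep(FALSE, m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

# Small cohort at the study's panel geometry (87 ROIs, 610 points, dt 2 s);
# cached per test run because generation + spectra dominate test time.
small_cohort <- local({
  cache <- NULL
  function(n_subjects = 12) {
    if (is.null(cache) || length(cache$panels) < n_subjects) {
      cfg <- generator_config(n_subjects = n_subjects)
      cache <<- list(config = cfg, panels = generate_cohort(cfg))
    }
    list(config = cache$config, panels = cache$panels[seq_len(n_subjects)])
  }
})
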