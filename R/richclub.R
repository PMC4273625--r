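#' Hub detection from degree and eigenvector centrality
#'
#' Hubs are nodes whose degree (in the thresholded group network) and
#' eigenvector centrality (in the unthresholded consistent edge matrix) are
#' both at least one standard deviation above the respective network mean.
#' Standard deviations are population (divide-by-n) SDs over nodes. When a
#' metric has zero spread (e.g. a regular graph's degrees) no node passes
#' that criterion.
#'
#' @param adjacency group network `adjacency` (degree criterion).
#' @param ce `consistency` matrix of kind "edge", unthresholded (centrality
#'   criterion).
#' @param part optional [partition()]; when given, hub participation
#'   coefficients and roles are included.
#' @return list of class `hub_report`: `hub_rois`, `degree_threshold`,
#'   `centrality_threshold`, and a data.frame `hubs` with per-hub degree,
#'   degree rank, centrality, centrality rank (and participation + role when
#'   a partition is supplied).
#' @export
detect_hubs <- function(adjacency, ce, part = NULL) {
  a <- adjacency_values(adjacency)
  cen <- eigenvector_centrality(ce)
  stopifnot(length(cen) == nrow(a))
  deg <- rowSums(a != 0)
  thr_d <- mean(deg) + pop_sd(deg)
  thr_c <- mean(cen) + pop_sd(cen)
  pass_d <- if (pop_sd(deg) == 0) rep(FALSE, length(deg)) else deg >= thr_d
  pass_c <- if (pop_sd(cen) == 0) rep(FALSE, length(cen)) else cen >= thr_c
  hubs <- which(pass_d & pass_c)
  tab <- data.frame(roi = hubs,
                    degree = deg[hubs],
                    degree_rank = rank(-deg, ties.method = "min")[hubs],
                    centrality = cen[hubs],
                    centrality_rank = rank(-cen, ties.method = "min")[hubs])
  if (!is.null(part) && length(hubs)) {
    pc <- participation_coefficient(a, part)
    tab$participation <- pc$participation[hubs]
    tab$role <- pc$role[hubs]
  }
  structure(list(hub_rois = hubs, degree_threshold = thr_d,
                 centrality_threshold = thr_c, hubs = tab),
            class = "hub_report")
}

#' Rich-club coefficient at level k
#'
#' \eqn{\Phi(k) = 2 E_k / (N_k (N_k - 1))} where \eqn{N_k} counts the nodes
#' with degree strictly greater than k and \eqn{E_k} the edges among them.
#' Undefined (NA) when fewer than 2 nodes qualify.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @param k degree level (>= 0).
#' @return \eqn{\Phi(k)} in [0, 1], or NA when undefined.
#' @export
rich_club_coefficient <- function(adjacency, k) {
  a <- adjacency_values(adjacency)
  deg <- rowSums(a != 0)
  keep <- deg > k
  n_k <- sum(keep)
  if (n_k < 2) return(NA_real_)
  e_k <- sum(a[keep, keep][upper.tri(a[keep, keep])] != 0)
  2 * e_k / (n_k * (n_k - 1))
}

# Full phi curve over k = 0..max degree, vectorized: an edge survives level k
# iff both endpoint degrees exceed k, i.e. iff min(deg_i, deg_j) > k.
rich_club_curve_values <- function(a, k_grid) {
  deg <- rowSums(a != 0)
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  edge_min <- pmin(deg[idx[, 1L]], deg[idx[, 2L]])
  vapply(k_grid, function(k) {
    n_k <- sum(deg > k)
    if (n_k < 2) return(NA_real_)
    2 * sum(edge_min > k) / (n_k * (n_k - 1))
  }, numeric(1))
}

#' Degree-preserving network randomization
#'
#' Randomizes the edge set by double-edge swaps that preserve every node's
#' degree, rejecting moves that would create self-loops or multi-edges.
#' Deterministic given a seed. Graphs without two independent edges (e.g. a
#' triangle) admit no valid swap and come back as an isomorphic copy, with a
#' warning that the randomization is partial.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @param n_swaps attempted swaps; defaults to 10 x the edge count.
#' @param seed RNG seed, or NULL to draw from the current RNG stream.
#' @return binary symmetric matrix with the same degree sequence.
#' @export
rewire_preserving_degree <- function(adjacency, n_swaps = NULL, seed = 1L) {
  a <- adjacency_values(adjacency)
  g <- as_igraph(a)
  m <- igraph::ecount(g)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  # fewer than 2 independent edges -> no double-edge swap can ever succeed
  el <- igraph::as_edgelist(g)
  independent <- m >= 2L &&
    any(vapply(seq_len(min(m, 50L)), function(i) {
      any(el[, 1L] != el[i, 1L] & el[, 1L] != el[i, 2L] &
            el[, 2L] != el[i, 1L] & el[, 2L] != el[i, 2L])
    }, logical(1)))
  do_rewire <- function() {
    if (!independent) {
      warning("graph admits no degree-preserving swap; returning an isomorphic copy",
              call. = FALSE)
      return(a)
    }
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = n_swaps))
    r <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    dimnames(r) <- dimnames(a)
    r
  }
  if (is.null(seed)) do_rewire() else with_seed(seed, do_rewire())
}

#' Rich-club regime against degree-preserving nulls
#'
#' Computes \eqn{\Phi(k)} over all k, builds a null distribution of
#' \eqn{\Phi_{randomized}(k)} from `n_null` degree-preserving rewirings, and
#' identifies the rich-club regime: the maximal contiguous k-range where the
#' observed \eqn{\Phi(k)} falls inside the upper `alpha` tail of the null
#' (per-k empirical order statistic). When several ranges qualify, the one
#' at highest k is the regime. The normalized curve divides \eqn{\Phi(k)} by
#' the null mean \eqn{\Phi_{meanrand}(k)}.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @param n_null number of randomized networks (study-scale default 1000).
#' @param alpha upper-tail level (default 0.01, i.e. the upper 1%).
#' @param seed RNG seed.
#' @param hub_rois optional hub set; when given, the report records the k
#'   values in the regime at which the surviving subgraph is exactly the hub
#'   set.
#' @return list of class `rich_club_curve`: `k_grid`, `phi`,
#'   `phi_rand_mean`, `phi_normalized`, `null_quantile`, `p_value` (add-one,
#'   per k), `regime` (integer k-range, possibly empty), `n_null`, `alpha`,
#'   and `hub_k` when `hub_rois` was supplied.
#' @export
rich_club_regime <- function(adjacency, n_null = 1000L, alpha = 0.01,
                             seed = 1L, hub_rois = NULL) {
  if (n_null < 100L) stop("n_null must be at least 100", call. = FALSE)
  a <- adjacency_values(adjacency)
  deg <- rowSums(a != 0)
  k_grid <- 0:max(deg)
  phi <- rich_club_curve_values(a, k_grid)
  null_phi <- matrix(NA_real_, n_null, length(k_grid))
  with_seed(seed, {
    for (b in seq_len(n_null)) {
      r <- rewire_preserving_degree(a, seed = NULL)
      stopifnot(identical(rowSums(r != 0), deg))  # degree preservation
      null_phi[b, ] <- rich_club_curve_values(r, k_grid)
    }
  })
  phi_rand_mean <- colMeans(null_phi)
  ord <- ceiling((1 - alpha) * n_null)
  null_q <- apply(null_phi, 2L, function(col) sort(col)[ord])
  p_k <- vapply(seq_along(k_grid), function(i) {
    if (is.na(phi[[i]])) return(NA_real_)
    (1 + sum(null_phi[, i] >= phi[[i]])) / (1 + n_null)
  }, numeric(1))
  signif <- !is.na(phi) & !is.na(null_q) & phi > null_q
  regime <- integer()
  if (any(signif)) {
    runs <- rle(signif)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    true_runs <- which(runs$values)
    last <- true_runs[[length(true_runs)]]  # highest-k range
    regime <- k_grid[starts[[last]]:ends[[last]]]
  }
  out <- list(k_grid = k_grid, phi = phi, phi_rand_mean = phi_rand_mean,
              phi_normalized = phi / phi_rand_mean,
              null_quantile = null_q, p_value = p_k, regime = regime,
              n_null = n_null, alpha = alpha)
  if (!is.null(hub_rois)) {
    out$hub_k <- k_grid[vapply(k_grid, function(k) {
      setequal(which(deg > k), hub_rois)
    }, logical(1))]
  }
  structure(out, class = "rich_club_curve")
}
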