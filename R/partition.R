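#' Construct a partition object
#'
#' @param labels community id per node; arbitrary labels are canonicalized to
#'   consecutive integers in order of first appearance.
#' @param modularity_q optional modularity of the partition on the graph it
#'   was detected in.
#' @return list of class `partition` with `labels`, `n_communities`,
#'   `modularity_q`.
#' @export
partition <- function(labels, modularity_q = NA_real_) {
  labels <- as.integer(factor(labels, levels = unique(labels)))
  structure(list(labels = labels,
                 n_communities = length(unique(labels)),
                 modularity_q = modularity_q),
            class = "partition")
}

partition_labels <- function(p) if (inherits(p, "partition")) p$labels else p

#' Newman modularity of a partition
#'
#' \eqn{Q = \sum_{u} [e_{uu} - (\sum_v e_{uv})^2]} where \eqn{e_{uv}} is the
#' fraction of all edges joining communities u and v (each undirected edge
#' counted once), so \eqn{\sum_v e_{uv}} equals the summed degree of
#' community u over twice the edge count.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @param part a [partition()] or label vector covering all nodes.
#' @return modularity Q (numeric scalar).
#' @export
modularity_q <- function(adjacency, part) {
  a <- adjacency_values(adjacency)
  labels <- partition_labels(part)
  stopifnot(length(labels) == nrow(a))
  ut <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  L <- nrow(ut)
  if (L == 0) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  comms <- sort(unique(labels))
  li <- labels[ut[, 1L]]
  lj <- labels[ut[, 2L]]
  e_uu <- vapply(comms, function(u) sum(li == u & lj == u), numeric(1)) / L
  deg <- rowSums(a != 0)
  a_u <- vapply(comms, function(u) sum(deg[labels == u]), numeric(1)) / (2 * L)
  sum(e_uu - a_u^2)
}

#' Louvain community detection with restarts
#'
#' Runs the Louvain modularity-maximization heuristic `n_restarts` times
#' under distinct random node orders and returns the partition with the
#' highest (weighted) modularity. Deterministic given the seed.
#'
#' @param matrix symmetric nonnegative matrix (binary adjacency or weighted,
#'   e.g. a consistency matrix), or an `adjacency`/`consistency` object.
#' @param n_restarts number of random restarts.
#' @param seed RNG seed.
#' @return A [partition()] with `modularity_q` set (weighted modularity on
#'   the supplied matrix).
#' @export
louvain_partition <- function(matrix, n_restarts = 100L, seed = 1L) {
  v <- adjacency_values(matrix)
  stopifnot(isSymmetric(unname(v)), all(v >= 0))
  diag(v) <- 0
  if (all(v == 0)) stop("cannot detect communities in an all-zero matrix", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  n <- nrow(v)
  w <- igraph::E(g)$weight
  best <- NULL
  best_q <- -Inf
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp)
      memb <- igraph::membership(cl)[perm]
      q <- igraph::modularity(g, memb, weights = w)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- memb
      }
    }
  })
  partition(best, modularity_q = best_q)
}

#' Consensus community assignment across subjects
#'
#' Builds the consistent assignment matrix Ca: for each subject, the
#' co-assignment indicator ICa(i, j) is 1 when ROIs i and j share a
#' community; Ca is the across-subject mean of the indicators (entries in
#' [0, 1]). The group partition is obtained by community detection on Ca.
#'
#' @param partitions list with one [partition()] (or label vector) per
#'   subject, all over the same ROI set.
#' @param n_restarts,seed passed to [louvain_partition()] on Ca.
#' @return list with `ca` (a `consistency` object of kind "assignment") and
#'   `partition` (the group [partition()]).
#' @export
consensus_assignment <- function(partitions, n_restarts = 100L, seed = 1L) {
  labs <- lapply(partitions, partition_labels)
  n <- length(labs[[1L]])
  if (!all(lengths(labs) == n)) stop("subject partitions cover different ROI sets", call. = FALSE)
  ca <- Reduce(`+`, lapply(labs, function(l) outer(l, l, "==") * 1)) /
    length(labs)
  diag(ca) <- 1
  ca_obj <- structure(list(values = ca, kind = "assignment", band = NULL),
                      class = "consistency")
  ca0 <- ca
  diag(ca0) <- 0
  list(ca = ca_obj,
       partition = louvain_partition(ca0, n_restarts = n_restarts, seed = seed))
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = -2 \sum_i \sum_j N_{ij} \log(N_{ij} N / N_i N_j) /
#'   [\sum_i N_i \log(N_i/N) + \sum_j N_j \log(N_j/N)]}
#' with natural logarithms, where \eqn{N_{ij}} counts nodes assigned to
#' community i of the first partition and j of the second. Identical
#' assignments give 1; independent assignments give 0. If both partitions
#' are the single-community partition the value is 1 by continuity; if
#' exactly one is, the value is 0.
#'
#' @param p1,p2 [partition()] objects or label vectors over the same nodes.
#' @return NMI in [0, 1].
#' @export
nmi <- function(p1, p2) {
  a <- partition_labels(p1)
  b <- partition_labels(p2)
  if (length(a) != length(b)) stop("partitions cover different node sets", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  if (length(ni) == 1L && length(nj) == 1L) return(1)
  num <- 0
  for (i in seq_along(ni)) {
    for (j in seq_along(nj)) {
      nij <- tab[i, j]
      if (nij > 0) num <- num + nij * log(nij * n / (ni[[i]] * nj[[j]]))
    }
  }
  den <- sum(ni * log(ni / n)) + sum(nj * log(nj / n))
  if (den == 0) return(if (num == 0) 1 else 0)
  val <- -2 * num / den
  # identical assignments give exactly 1; guard the identity against float
  # roundoff in the entropy sums
  if (abs(val - 1) < 1e-12) val <- 1
  min(max(val, 0), 1)
}

#' Permutation significance of partition similarity
#'
#' Tests the NMI between community structures of two networks (or between a
#' network's communities and an external reference partition) against nulls
#' built from randomized networks. Each replicate rewires the network(s) by
#' degree-preserving double-edge swaps, re-detects communities, and computes
#' the NMI; p-values use the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_null).
#'
#' For an external reference partition a second null from density-matched
#' Erdos-Renyi random graphs is computed as well; the reported `p_value` is
#' the conservative (larger) of the two, and both null distributions are
#' returned.
#'
#' @param ag an `adjacency` object (group network).
#' @param reference a second `adjacency` object, or a [partition()]/label
#'   vector used as an external reference.
#' @param n_null number of null replicates (>= 100; the study-scale default
#'   is 10000).
#' @param seed RNG seed.
#' @param n_restarts Louvain restarts for the observed partitions.
#' @param null_restarts Louvain restarts inside null replicates (kept small
#'   because each replicate repeats detection).
#' @return list of class `nmi_result`: `nmi`, `p_value`, `n_null`, plus
#'   `null_rewired` (and `null_random`, `p_rewired`, `p_random` for an
#'   external reference).
#' @export
nmi_significance <- function(ag, reference, n_null = 10000L, seed = 1L,
                             n_restarts = 100L, null_restarts = 1L) {
  if (n_null < 100L) stop("n_null must be at least 100", call. = FALSE)
  a <- adjacency_values(ag)
  external <- !(is.list(reference) && !is.null(reference$values)) &&
    !(is.matrix(reference))
  p_obs_a <- louvain_partition(a, n_restarts = n_restarts, seed = seed)
  if (external) {
    ref_labels <- partition_labels(reference)
    observed <- nmi(p_obs_a, ref_labels)
    m_edges <- sum(a[upper.tri(a)] != 0)
    nulls <- with_seed(seed + 1L, {
      rew <- numeric(n_null)
      rnd <- numeric(n_null)
      for (b in seq_len(n_null)) {
        ra <- rewire_preserving_degree(a, seed = NULL)
        rew[b] <- nmi(louvain_partition(ra, n_restarts = null_restarts,
                                        seed = sample.int(2^30, 1)), ref_labels)
        er <- igraph::sample_gnm(nrow(a), m_edges)
        rnd[b] <- nmi(partition(igraph::membership(igraph::cluster_louvain(er))),
                      ref_labels)
      }
      list(rew = rew, rnd = rnd)
    })
    p_rew <- (1 + sum(nulls$rew >= observed)) / (1 + n_null)
    p_rnd <- (1 + sum(nulls$rnd >= observed)) / (1 + n_null)
    structure(list(nmi = observed, p_value = max(p_rew, p_rnd),
                   p_rewired = p_rew, p_random = p_rnd,
                   null_rewired = nulls$rew, null_random = nulls$rnd,
                   n_null = n_null),
              class = "nmi_result")
  } else {
    b_mat <- adjacency_values(reference)
    p_obs_b <- louvain_partition(b_mat, n_restarts = n_restarts, seed = seed + 7L)
    observed <- nmi(p_obs_a, p_obs_b)
    nulls <- with_seed(seed + 1L, {
      vapply(seq_len(n_null), function(k) {
        ra <- rewire_preserving_degree(a, seed = NULL)
        rb <- rewire_preserving_degree(b_mat, seed = NULL)
        nmi(louvain_partition(ra, n_restarts = null_restarts,
                              seed = sample.int(2^30, 1)),
            louvain_partition(rb, n_restarts = null_restarts,
                              seed = sample.int(2^30, 1)))
      }, numeric(1))
    })
    p <- (1 + sum(nulls >= observed)) / (1 + n_null)
    structure(list(nmi = observed, p_value = p, null_rewired = nulls,
                   n_null = n_null),
              class = "nmi_result")
  }
}
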