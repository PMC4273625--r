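#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' \eqn{E = \frac{1}{n} \sum_{i} \frac{\sum_{j \ne i} d_{ij}^{-1}}{n - 1}},
#' with path lengths from breadth-first search; unreachable pairs contribute
#' 0 (1/infinity), so disconnected networks are handled without error.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @return list of class `efficiency` with `value` in [0, 1] and `n`.
#' @export
global_efficiency <- function(adjacency) {
  a <- adjacency_values(adjacency)
  n <- nrow(a)
  stopifnot(n >= 2)
  d <- igraph::distances(as_igraph(a))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  structure(list(value = sum(inv) / (n * (n - 1)), n = n),
            class = "efficiency")
}

#' Eigenvector centrality by power iteration
#'
#' Dominant-eigenvector entries of a nonnegative symmetric weight matrix
#' (typically the unthresholded consistent edge matrix Ce), computed by
#' power iteration with a diagonal shift (which leaves eigenvectors
#' unchanged but guarantees a nonnegative dominant eigenvalue). The result
#' is nonnegative and normalized to unit maximum.
#'
#' @param matrix nonnegative symmetric matrix or `consistency` object.
#' @param tol convergence tolerance on the max-normalized iterate.
#' @param max_iter iteration cap.
#' @return numeric vector of centralities in [0, 1], max = 1.
#' @export
eigenvector_centrality <- function(matrix, tol = 1e-10, max_iter = 100000L) {
  m <- adjacency_values(matrix)
  stopifnot(all(m >= 0), isSymmetric(unname(m)))
  if (all(m == 0)) stop("centrality is undefined for an all-zero matrix", call. = FALSE)
  n <- nrow(m)
  shift <- max(rowSums(m)) / 2
  ms <- m + diag(shift, n)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v_new <- drop(ms %*% v)
    v_new <- v_new / max(v_new)
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  stop("power iteration did not converge within ", max_iter, " iterations",
       call. = FALSE)
}

#' Participation coefficient and node roles
#'
#' \eqn{P_i = 1 - \sum_{s} (\kappa_{is} / k_i)^2} where \eqn{k_i} is the
#' degree of node i and \eqn{\kappa_{is}} its number of edges into community
#' s. P is 0 when all edges stay within the node's own community and
#' approaches (but never reaches) 1 as edges spread evenly over many
#' communities; with \eqn{N_M} communities \eqn{P \le 1 - 1/N_M}. Isolated
#' nodes get P = 0. Roles follow the conventional cut points: provincial
#' (P <= 0.30), connector (0.30 < P <= 0.75), kinless (P > 0.75); with three
#' communities P cannot exceed 2/3, so kinless nodes cannot occur.
#'
#' @param adjacency an `adjacency` object or binary symmetric matrix.
#' @param part a [partition()] or label vector covering all nodes.
#' @return data.frame with columns `roi`, `degree`, `participation`, `role`.
#' @export
participation_coefficient <- function(adjacency, part) {
  a <- adjacency_values(adjacency)
  labels <- partition_labels(part)
  stopifnot(length(labels) == nrow(a))
  comms <- sort(unique(labels))
  ind <- outer(labels, comms, "==") * 1
  kappa <- (a != 0) %*% ind
  k <- rowSums(a != 0)
  p <- 1 - rowSums((kappa / pmax(k, 1))^2)
  p[k == 0] <- 0
  role <- cut(p, breaks = c(-Inf, 0.30, 0.75, Inf),
              labels = c("provincial", "connector", "kinless"))
  data.frame(roi = seq_len(nrow(a)), degree = k, participation = p,
             role = as.character(role))
}
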