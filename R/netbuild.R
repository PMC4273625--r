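#' Threshold a coherence matrix at a target sparsity
#'
#' Sparsity S is the fraction of realized edges out of all possible node
#' pairs. The m = floor(S n(n-1)/2) strongest off-diagonal pairs become
#' edges, so the realized edge count equals the target exactly and never
#' exceeds the requested density. Ties at the cutoff are broken
#' deterministically by ascending (i, j) index pairs.
#'
#' @param matrix a `coh_matrix` (see [band_average()]), a `consistency`
#'   object, or a plain symmetric numeric matrix.
#' @param S sparsity in (0, 1].
#' @return list of class `adjacency` with fields `values` (binary symmetric
#'   matrix, zero diagonal), `band` (if known), `sparsity`.
#' @export
sparsity_threshold <- function(matrix, S) {
  if (!(S > 0 && S <= 1)) stop("S must lie in (0, 1]", call. = FALSE)
  bd <- if (is.list(matrix)) matrix$band else NULL
  v <- if (is.list(matrix)) matrix$values else matrix
  n <- nrow(v)
  n_pairs <- n * (n - 1) / 2
  m <- floor(S * n_pairs)
  if (m == 0) stop("threshold retains no edges", call. = FALSE)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  ord <- order(-v[ut], ut[, 1L], ut[, 2L])
  keep <- ut[ord[seq_len(m)], , drop = FALSE]
  a <- Matrix_zero(n)
  a[keep] <- 1L
  a[keep[, c(2L, 1L), drop = FALSE]] <- 1L
  dimnames(a) <- dimnames(v)
  structure(list(values = a, band = bd, sparsity = S), class = "adjacency")
}

Matrix_zero <- function(n) matrix(0L, n, n)

adjacency_values <- function(x) {
  if (inherits(x, "adjacency") || (is.list(x) && !is.null(x$values))) x$values else x
}

as_igraph <- function(x, weighted = FALSE) {
  v <- adjacency_values(x)
  igraph::graph_from_adjacency_matrix(v, mode = "undirected",
                                      weighted = if (weighted) TRUE else NULL,
                                      diag = FALSE)
}

#' Bootstrap null distribution of band-averaged coherence for one ROI pair
#'
#' Builds surrogate pairs by circularly time-shifting one signal of the pair
#' by a uniformly random offset of at least one Welch segment (preserving its
#' autocorrelation while destroying alignment with the other signal), or by
#' phase randomization, and recomputes the band-averaged coherence `n_boot`
#' times.
#'
#' @param panel a [ts_panel()].
#' @param pair two ROI column indices.
#' @param bd a [band()].
#' @param n_boot number of surrogate replicates (>= 100).
#' @param alpha significance level for the critical value.
#' @param seed RNG seed.
#' @param settings [spectral_settings()].
#' @param method `"shift"` (circular time shift, default) or `"phase"`
#'   (phase randomization).
#' @return list with fields `values` (the n_boot surrogate coherences),
#'   `critical` (empirical 1 - alpha quantile), `observed`, `alpha`.
#' @export
coherence_null <- function(panel, pair, bd, n_boot = 10000L, alpha = 0.05,
                           seed = 1L, settings = spectral_settings(),
                           method = c("shift", "phase")) {
  method <- match.arg(method)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  x <- panel$values[, pair[[1L]]]
  y <- panel$values[, pair[[2L]]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant signal in the requested pair", call. = FALSE)
  }
  n <- length(y)
  L <- settings$segment_length
  observed <- pair_band_coherence(x, y, panel$dt, bd, settings)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ys <- if (method == "shift") {
        off <- sample.int(n - 2L * L, 1L) + L  # offset in [L+1, n-L]
        c(y[(off + 1L):n], y[1:off])
      } else {
        phase_randomize(y)
      }
      pair_band_coherence(x, ys, panel$dt, bd, settings)
    }, numeric(1))
  })
  list(values = vals,
       critical = stats::quantile(vals, 1 - alpha, names = FALSE,
                                  type = 1),
       observed = observed, alpha = alpha)
}

# Surrogate with the same power spectrum but uniformly random phases.
# Conjugate symmetry is rebuilt so the inverse transform is real; DC and (for
# even n) the Nyquist bin keep their original values.
phase_randomize <- function(y) {
  n <- length(y)
  f <- stats::fft(y)
  half <- 2:((n + 1) %/% 2)
  ph <- stats::runif(length(half), 0, 2 * pi)
  f[half] <- Mod(f[half]) * exp(1i * ph)
  f[n + 2L - half] <- Conj(f[half])
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Select the sparsity floor supported by the bootstrap nulls
#'
#' A sparsity S is admissible when, for every subject, the weakest coherence
#' retained at S (the m-th ranked off-diagonal value) exceeds its null
#' critical value, i.e. the edge-defining coherence cutoff is significant at
#' the null's level for all subjects. Returns the largest admissible S of the
#' grid and flags the entries that fail.
#'
#' @param matrices list over subjects of `coh_matrix` objects (one band).
#' @param s_grid strictly increasing sparsity thresholds in (0, 1).
#' @param nulls either a single critical value (pooled null), a vector with
#'   one critical value per subject, or a list of per-subject matrices of
#'   per-pair critical values.
#' @return list with `selected` (largest admissible S), `admissible`
#'   (logical per grid entry), `detail` (subject x S matrix of pass flags).
#' @export
validate_sparsity_floor <- function(matrices, s_grid, nulls) {
  stopifnot(all(diff(s_grid) > 0), all(s_grid > 0 & s_grid < 1))
  n_sub <- length(matrices)
  detail <- matrix(NA, n_sub, length(s_grid),
                   dimnames = list(NULL, as.character(s_grid)))
  for (si in seq_along(s_grid)) {
    S <- s_grid[[si]]
    for (su in seq_len(n_sub)) {
      v <- matrices[[su]]$values
      n <- nrow(v)
      m <- floor(S * n * (n - 1) / 2)
      ut <- v[upper.tri(v)]
      cutoff <- sort(ut, decreasing = TRUE)[[m]]
      crit <- if (is.list(nulls)) {
        # per-pair critical values: the weakest retained edge must beat its
        # own pair's null; conservatively use the largest critical value
        # among retained pairs at this S
        cm <- nulls[[su]]
        max(cm[upper.tri(cm)][ut >= cutoff])
      } else if (length(nulls) == n_sub) {
        nulls[[su]]
      } else {
        nulls[[1L]]
      }
      detail[su, si] <- cutoff > crit
    }
  }
  admissible <- apply(detail, 2L, all)
  if (!any(admissible)) {
    stop("no sparsity in the grid is admissible; per-subject diagnostics:\n",
         paste(utils::capture.output(print(detail)), collapse = "\n"),
         call. = FALSE)
  }
  list(selected = max(s_grid[admissible]), admissible = admissible,
       detail = detail)
}

#' Consistent edge matrix Ce
#'
#' Entrywise mean of the subjects' binary adjacency matrices: entry (i, j) is
#' the fraction of subjects exhibiting edge i-j, bounded in [0, 1].
#'
#' @param adjacencies list of `adjacency` objects for one band.
#' @return list of class `consistency` with `values`, `kind = "edge"`,
#'   `band`.
#' @export
consistency_matrix <- function(adjacencies) {
  stopifnot(length(adjacencies) >= 1L)
  bands <- lapply(adjacencies, function(a) a$band)
  if (!all(vapply(bands, function(b) identical(b, bands[[1L]]), logical(1)))) {
    stop("adjacency matrices come from mixed bands", call. = FALSE)
  }
  vals <- Reduce(`+`, lapply(adjacencies, adjacency_values)) / length(adjacencies)
  structure(list(values = vals, kind = "edge", band = bands[[1L]]),
            class = "consistency")
}

#' Group-level network from the consistent edge matrix
#'
#' Applies the same sparsity-thresholding rule as [sparsity_threshold()] to
#' Ce and reports whether the resulting group network is connected
#' (breadth-first reachability); connectedness is flagged, not enforced.
#'
#' @param ce a `consistency` matrix of kind "edge".
#' @param S sparsity in (0, 1].
#' @return list with `adjacency` (the group network A^g) and `connected`.
#' @export
group_network <- function(ce, S) {
  adj <- sparsity_threshold(ce, S)
  g <- as_igraph(adj)
  list(adjacency = adj, connected = igraph::is_connected(g))
}
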