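#' Paired two-tailed t-test
#'
#' One-sample t-test on the paired differences x - y, two-tailed p from the
#' t distribution with n - 1 degrees of freedom. Zero-variance differences
#' are reported as degenerate with p = 1 rather than an error, since grids
#' of metric comparisons routinely contain identical cells.
#'
#' @param x,y per-subject values, equal lengths >= 3.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Benjamini-Yekutieli FDR significance flags
#'
#' Step-up procedure with the harmonic-sum correction
#' \eqn{c(m) = \sum_{i=1}^m 1/i}: the largest rank r with
#' \eqn{p_{(r)} \le r q / (m c(m))} determines the rejections, valid under
#' arbitrary dependence of the p-values.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return logical vector of significance flags, same order as `p_values`.
#' @export
fdr_by <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BY") <= q
}

#' Band-wise comparison of subject-level graph metrics
#'
#' For each (metric, sparsity) cell, runs a paired two-tailed t-test of the
#' first band against the second across subjects, then applies
#' Benjamini-Yekutieli FDR control jointly over all cells (with the default
#' 5-threshold grid and 2 metrics this is the 10-comparison family).
#'
#' @param metrics long data.frame with columns `subject`, `band`, `sparsity`,
#'   `metric`, `value`; `band` must have exactly two levels.
#' @param q FDR level.
#' @return list of class `comparison_report`: `table` (one row per cell with
#'   band means, t, p, significance flag), `m` (number of comparisons),
#'   `q`, `bands` (band order used: first minus second).
#' @export
compare_bands <- function(metrics, q = 0.05) {
  need <- c("subject", "band", "sparsity", "metric", "value")
  stopifnot(all(need %in% names(metrics)))
  bands <- unique(as.character(metrics$band))
  if (length(bands) != 2L) stop("exactly two bands are required", call. = FALSE)
  subjects <- sort(unique(metrics$subject))
  cells <- unique(metrics[, c("metric", "sparsity")])
  cells <- cells[order(cells$metric, cells$sparsity), , drop = FALSE]
  # completeness: every subject must appear in every (band, metric, S) cell
  missing <- character()
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    mt <- cells$metric[[r]]
    S <- cells$sparsity[[r]]
    get_band <- function(bd) {
      sub <- metrics[metrics$metric == mt & metrics$sparsity == S &
                       metrics$band == bd, ]
      sub$value[match(subjects, sub$subject)]
    }
    v1 <- get_band(bands[[1L]])
    v2 <- get_band(bands[[2L]])
    if (anyNA(v1) || anyNA(v2)) {
      missing <- c(missing, sprintf("%s @ S=%g", mt, S))
      next
    }
    tt <- paired_ttest(v1, v2)
    rows[[r]] <- data.frame(metric = mt, sparsity = S,
                            mean_1 = mean(v1), mean_2 = mean(v2),
                            t = tt$t, df = tt$df, p = tt$p,
                            degenerate = tt$degenerate)
  }
  if (length(missing)) {
    stop("incomplete metric grid; missing cells: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "mean_1"] <- paste0("mean_", bands[[1L]])
  names(tab)[names(tab) == "mean_2"] <- paste0("mean_", bands[[2L]])
  tab$significant <- fdr_by(tab$p, q = q)
  structure(list(table = tab, m = nrow(tab), q = q, bands = bands),
            class = "comparison_report")
}
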