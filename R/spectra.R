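#' Spectral estimation settings
#'
#' Settings for the Welch coherence estimator. Defaults resolve 0.02 Hz-wide
#' bands from 610 samples at dt = 2 s: segment length 128 samples, 50%
#' segment overlap, Hann taper, per-segment linear detrend (frequency
#' resolution 1/(128 dt), about 0.0039 Hz at dt = 2, i.e. ~5 grid points per
#' 0.02 Hz band).
#'
#' @param segment_length samples per Welch segment.
#' @param overlap fractional overlap between successive segments in [0, 1).
#' @param taper taper name; only `"hann"` is implemented.
#' @param detrend linearly detrend each segment before tapering.
#' @return A list of class `spectral_settings`.
#' @export
spectral_settings <- function(segment_length = 128L, overlap = 0.5,
                              taper = "hann", detrend = TRUE) {
  stopifnot(segment_length >= 8L, overlap >= 0, overlap < 1)
  taper <- match.arg(taper, "hann")
  structure(list(segment_length = as.integer(segment_length),
                 overlap = overlap, taper = taper, detrend = detrend),
            class = "spectral_settings")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Remove per-column linear trend (least squares on an intercept + time).
detrend_linear <- function(x) {
  n <- nrow(x)
  t0 <- seq_len(n) - (n + 1) / 2
  slope <- crossprod(t0, x) / sum(t0^2)
  x - rep(colMeans(x), each = n) - outer(t0, drop(slope))
}

welch_segment_starts <- function(n, settings) {
  L <- settings$segment_length
  step <- max(1L, as.integer(round(L * (1 - settings$overlap))))
  if (n < L) return(integer())
  seq.int(1L, n - L + 1L, by = step)
}

# Tapered, detrended segment FFTs: list of (nfreq x nroi) complex matrices,
# positive frequencies only (DC dropped, Nyquist kept).
segment_ffts <- function(values, settings) {
  L <- settings$segment_length
  starts <- welch_segment_starts(nrow(values), settings)
  w <- hann_window(L)
  keep <- 2:(L %/% 2 + 1)
  lapply(starts, function(s) {
    seg <- values[s:(s + L - 1L), , drop = FALSE]
    if (settings$detrend) seg <- detrend_linear(seg)
    stats::mvfft(seg * w)[keep, , drop = FALSE]
  })
}

#' Pairwise magnitude-squared coherence spectrum
#'
#' Estimates the full ROI x ROI x frequency array of magnitude-squared
#' coherence \eqn{C_{xy}(\lambda) = |P_{xy}(\lambda)|^2 /
#' (P_{xx}(\lambda) P_{yy}(\lambda))} by Welch's method: cross- and
#' auto-spectra are averaged over tapered, overlapping, detrended segments
#' and combined per the definition. Coherence is bounded in [0, 1] and the
#' diagonal is exactly 1.
#'
#' @param panel a [ts_panel()].
#' @param settings a [spectral_settings()].
#' @return A list of class `coh_spectrum` with fields `values`
#'   (roi x roi x freq array), `freqs` (Hz), `settings`.
#' @export
coherence_spectrum <- function(panel, settings = spectral_settings()) {
  stopifnot(inherits(panel, "ts_panel"))
  x <- panel$values
  vars <- apply(x, 2L, stats::var)
  if (any(vars == 0)) {
    nm <- colnames(x)
    bad <- which(vars == 0)[[1L]]
    lab <- if (!is.null(nm)) nm[[bad]] else as.character(bad)
    stop("constant (zero-variance) signal for ROI ", lab, call. = FALSE)
  }
  ffts <- segment_ffts(x, settings)
  if (length(ffts) < 2L) {
    stop("panel too short: fewer than 2 Welch segments fit under the settings",
         call. = FALSE)
  }
  L <- settings$segment_length
  p <- ncol(x)
  freqs <- (1:(L %/% 2)) / (L * panel$dt)
  nf <- length(freqs)
  cross <- array(0 + 0i, dim = c(p, p, nf))
  for (f in ffts) {
    for (k in seq_len(nf)) {
      v <- f[k, ]
      cross[, , k] <- cross[, , k] + outer(v, Conj(v))
    }
  }
  coh <- array(NA_real_, dim = c(p, p, nf),
               dimnames = list(colnames(x), colnames(x), NULL))
  for (k in seq_len(nf)) {
    auto <- Re(diag(cross[, , k]))
    coh[, , k] <- Mod(cross[, , k])^2 / outer(auto, auto)
    diag(coh[, , k]) <- 1
  }
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(values = coh, freqs = freqs, settings = settings,
                 dt = panel$dt),
            class = "coh_spectrum")
}

#' Construct a frequency band
#' @param lo,hi band edges in Hz, 0 < lo < hi.
#' @param closed_upper whether the upper edge belongs to the band (used for
#'   the last band of an overlapping ladder).
#' @return A list of class `band` with fields `lo`, `hi`, `center`.
#' @export
band <- function(lo, hi, closed_upper = FALSE) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi, center = (lo + hi) / 2,
                 closed_upper = isTRUE(closed_upper)),
            class = "band")
}

#' @export
format.band <- function(x, ...) sprintf("[%g, %g] Hz", x$lo, x$hi)

#' Ladder of narrow overlapping frequency bands
#'
#' Bands start at `f_lo`, advance by `width * (1 - overlap_fraction)` and are
#' emitted while the band's upper edge stays within `f_hi` (to 1e-12). The
#' default analysis uses 0.01-0.25 Hz, width 0.02 Hz and 50% overlap, which
#' yields 23 bands with centers 0.02, 0.03, ..., 0.24 Hz.
#'
#' @param f_lo,f_hi frequency range in Hz.
#' @param width band width in Hz.
#' @param overlap_fraction fractional overlap between successive bands.
#' @return list of [band()] objects; the last band has a closed upper edge.
#' @export
make_bands <- function(f_lo = 0.01, f_hi = 0.25, width = 0.02,
                       overlap_fraction = 0.5) {
  if (!(f_lo < f_hi) || overlap_fraction < 0 || overlap_fraction >= 1 ||
      width <= 0 || width > f_hi - f_lo + 1e-12) {
    stop("invalid band ladder arguments", call. = FALSE)
  }
  step <- width * (1 - overlap_fraction)
  lo <- f_lo
  bands <- list()
  while (lo + width <= f_hi + 1e-12) {
    bands[[length(bands) + 1L]] <- band(lo, lo + width)
    lo <- lo + step
  }
  bands[[length(bands)]]$closed_upper <- TRUE
  bands
}

band_mask <- function(freqs, bd) {
  m <- freqs >= bd$lo - 1e-12 & freqs < bd$hi - 1e-12
  if (isTRUE(bd$closed_upper)) m <- m | abs(freqs - bd$hi) <= 1e-12
  m
}

#' Band-averaged coherence matrix
#'
#' Entrywise mean of the coherence spectrum over the frequency-grid points
#' inside the band (half-open membership \code{[lo, hi)}; the final band of a
#' ladder additionally includes its upper edge).
#'
#' @param spectrum a `coh_spectrum`.
#' @param bd a [band()].
#' @return A list of class `coh_matrix` with fields `values`, `band`.
#' @export
band_average <- function(spectrum, bd) {
  stopifnot(inherits(spectrum, "coh_spectrum"), inherits(bd, "band"))
  m <- band_mask(spectrum$freqs, bd)
  if (!any(m)) {
    stop("no frequency-grid points fall inside band ", format(bd),
         call. = FALSE)
  }
  vals <- apply(spectrum$values[, , m, drop = FALSE], c(1L, 2L), mean)
  diag(vals) <- 1
  structure(list(values = vals, band = bd), class = "coh_matrix")
}

#' Intra- and inter-system coherence curves
#'
#' For each band, averages band-averaged coherence over unordered ROI pairs
#' belonging to the same functional system (intra-system curve) and to
#' different systems (inter-system curve); the diagonal is excluded.
#'
#' @param x a `coh_spectrum`, or a list of `coh_matrix` objects (one per
#'   band, same order as `bands`).
#' @param roi_table an ROI table whose `system` column labels the columns of
#'   the panel, in order.
#' @param bands list of [band()] objects.
#' @return data.frame with columns `center`, `lo`, `hi`, `intra`, `inter`
#'   (NA where a category has no pairs).
#' @export
system_curves <- function(x, roi_table, bands = make_bands()) {
  systems <- roi_table$system
  if (inherits(x, "coh_spectrum")) {
    if (dim(x$values)[1L] != length(systems)) {
      stop("ROI count of spectrum does not match the ROI table", call. = FALSE)
    }
    mats <- lapply(bands, function(b) band_average(x, b))
  } else {
    mats <- x
    stopifnot(length(mats) == length(bands))
  }
  same <- outer(systems, systems, "==")
  ut <- upper.tri(same)
  intra_idx <- ut & same
  inter_idx <- ut & !same
  res <- lapply(seq_along(bands), function(i) {
    v <- mats[[i]]$values
    data.frame(center = bands[[i]]$center, lo = bands[[i]]$lo,
               hi = bands[[i]]$hi,
               intra = if (any(intra_idx)) mean(v[intra_idx]) else NA_real_,
               inter = if (any(inter_idx)) mean(v[inter_idx]) else NA_real_)
  })
  do.call(rbind, res)
}

# Band-averaged coherence of a single signal pair; shares the Welch machinery
# with coherence_spectrum but avoids the full p x p array. Used by the
# bootstrap null, where it is called thousands of times.
pair_band_coherence <- function(x, y, dt, bd, settings = spectral_settings()) {
  L <- settings$segment_length
  starts <- welch_segment_starts(length(x), settings)
  if (length(starts) < 2L) stop("signals too short for the settings", call. = FALSE)
  w <- hann_window(L)
  freqs <- (1:(L %/% 2)) / (L * dt)
  keepf <- which(band_mask(freqs, bd))
  if (!length(keepf)) stop("no grid points in band ", format(bd), call. = FALSE)
  keep <- keepf + 1L  # skip DC bin
  pxx <- pyy <- numeric(length(keepf))
  pxy <- complex(length(keepf))
  for (s in starts) {
    seg <- cbind(x[s:(s + L - 1L)], y[s:(s + L - 1L)])
    if (settings$detrend) seg <- detrend_linear(seg)
    f <- stats::mvfft(seg * w)[keep, , drop = FALSE]
    pxx <- pxx + Mod(f[, 1L])^2
    pyy <- pyy + Mod(f[, 2L])^2
    pxy <- pxy + f[, 1L] * Conj(f[, 2L])
  }
  mean(Mod(pxy)^2 / (pxx * pyy))
}
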