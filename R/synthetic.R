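#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-subject ROI time-series cohort with planted,
#' band-specific community coupling and connector-hub wiring. Each frequency
#' band carries one independent band-limited latent process per community.
#' An ROI's signal is its community's latent scaled by the per-band coupling
#' strength `alpha` and a per-ROI coupling weight, plus (for hub ROIs) the
#' latent of one designated other community scaled by `beta` (hubs are
#' assigned target communities round-robin, so bridges are spread over all
#' community pairs), plus white noise. Per-ROI weights and per-subject,
#' per-band coupling factors introduce the heterogeneity seen in real
#' cohorts: broad coherence distributions within each class of ROI pair and
#' between-subject variability in band engagement.
#'
#' Defaults emulate the study conditions of the resting-state analysis the
#' package implements: 87 ROIs, 28 subjects, 610 time points at dt = 2 s,
#' elevated coherence in 0.01-0.03 Hz (VLF) and 0.07-0.09 Hz (LF), three
#' planted communities with stronger community coupling — hence stronger
#' segregation — in the VLF band, and four connector hubs per community.
#'
#' @param n_rois,n_subjects,n_timepoints,dt panel dimensions and sampling
#'   interval (seconds).
#' @param bands named list; each element is a list with fields `lo`, `hi`
#'   (Hz), `alpha` (community coupling amplitude, >= 0; either a scalar or
#'   one value per community, allowing a band to engage the communities
#'   unevenly) and `beta` (hub cross-community bridge amplitude, >= 0).
#' @param planted_partition integer community label per ROI, or a named list
#'   of per-band label vectors (names matching `bands`).
#' @param hub_rois ROI ids receiving a cross-community bridge.
#' @param noise_sd white-noise standard deviation (> 0).
#' @param weight_range range of the uniform per-ROI coupling weights.
#' @param subject_sd standard deviation of the per-subject, per-band
#'   log-normal coupling factor (0 disables between-subject variability).
#' @param seed master seed; per-subject streams use fixed offsets from it.
#' @param confounds optional list of sinusoidal confounds, each a list with
#'   fields `freq` (Hz) and `amplitude`; see [nirs_preset()].
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_rois = 87L, n_subjects = 28L,
                             n_timepoints = 610L, dt = 2,
                             bands = list(
                               vlf = list(lo = 0.01, hi = 0.03, alpha = 0.55, beta = 0.50),
                               lf  = list(lo = 0.07, hi = 0.09,
                                          alpha = c(0.60, 0.42, 0.32), beta = 0.50)
                             ),
                             planted_partition = rep(seq_len(3L),
                                                     length.out = n_rois),
                             hub_rois = default_hub_rois(planted_partition),
                             noise_sd = 1,
                             weight_range = c(0.7, 1.3),
                             subject_sd = 0.2,
                             seed = 20140187L,
                             confounds = list()) {
  nyquist <- 1 / (2 * dt)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!(b$lo > 0 && b$hi > b$lo)) stop("band ", nm, ": need 0 < lo < hi", call. = FALSE)
    if (b$hi >= nyquist) {
      stop(sprintf("band %s [%g, %g] Hz lies at or above the Nyquist frequency %g Hz",
                   nm, b$lo, b$hi, nyquist), call. = FALSE)
    }
    if (any(b$alpha < 0) || b$beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  }
  parts <- planted_partition
  if (!is.list(parts)) parts <- stats::setNames(rep(list(parts), length(bands)),
                                               names(bands))
  for (nm in names(bands)) {
    if (length(parts[[nm]]) != n_rois) {
      stop("planted partition must cover every ROI exactly once", call. = FALSE)
    }
  }
  # the narrowest band must hold at least 2 bins of the default spectral grid
  L <- spectral_settings()$segment_length
  if (n_timepoints < 1.5 * L) {
    stop("n_timepoints too short: fewer than 2 Welch segments under the default spectral settings",
         call. = FALSE)
  }
  df <- 1 / (L * dt)
  narrowest <- min(vapply(bands, function(b) b$hi - b$lo, numeric(1)))
  if (narrowest < 2 * df) {
    stop("n_timepoints/dt too coarse to resolve the narrowest band: fewer than 2 spectral bins inside it",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(n_rois = as.integer(n_rois),
                 n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints), dt = dt,
                 bands = bands, planted_partition = parts,
                 hub_rois = as.integer(hub_rois), noise_sd = noise_sd,
                 weight_range = weight_range, subject_sd = subject_sd,
                 seed = as.integer(seed), confounds = confounds),
            class = "generator_config")
}

# Four connector hubs per planted community (fewer if a community is small).
default_hub_rois <- function(planted_partition, per_community = 4L) {
  p <- if (is.list(planted_partition)) planted_partition[[1L]] else planted_partition
  unlist(lapply(sort(unique(p)), function(cc) {
    utils::head(which(p == cc), per_community)
  }))
}

# Round-robin bridge targets: the j-th hub of community c bridges to the
# j-th other community (cyclically), so bridges cover all community pairs.
hub_targets <- function(part, hub_rois) {
  comms <- sort(unique(part))
  targets <- integer(length(hub_rois))
  for (cc in comms) {
    idx <- which(part[hub_rois] == cc)
    others <- comms[comms != cc]
    if (length(others)) {
      targets[idx] <- others[((seq_along(idx) - 1L) %% length(others)) + 1L]
    } else {
      targets[idx] <- cc
    }
  }
  stats::setNames(targets, hub_rois)
}

#' NIRS-like preset: fast sampling plus physiological confounds
#'
#' Returns a copy of the config with dt = 0.1 s and two sinusoidal
#' confounds at 0.3 Hz (respiratory) and 1 Hz (cardiac), the typical
#' physiological peaks seen in near-infrared spectroscopy hemodynamics.
#'
#' @param config a [generator_config()].
#' @param amplitude confound amplitude in signal units.
#' @return modified `generator_config`.
#' @export
nirs_preset <- function(config, amplitude = 0.5) {
  config$dt <- 0.1
  config$confounds <- list(list(freq = 0.3, amplitude = amplitude),
                           list(freq = 1.0, amplitude = amplitude))
  config
}

# Unit-variance band-limited noise: zero-phase (forward-backward) Butterworth
# band-pass of white noise; edge transients are trimmed.
bandlimited_noise <- function(n, lo, hi, dt) {
  nyq <- 1 / (2 * dt)
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 200L))[101:(n + 100L)]
  x / stats::sd(x)
}

#' Generate a synthetic multi-subject cohort
#'
#' Deterministic given the config seed: subject s is generated from seed
#' `seed + 1000 * s`, so subjects are independent streams and cohorts can be
#' regenerated subject by subject.
#'
#' @param config a [generator_config()].
#' @return list of [ts_panel()] objects, one per subject.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  lapply(seq_len(config$n_subjects), function(s) {
    with_seed(config$seed + 1000L * s, generate_subject(config, s))
  })
}

generate_subject <- function(config, s) {
  n <- config$n_timepoints
  p <- config$n_rois
  w <- stats::runif(p, config$weight_range[[1L]], config$weight_range[[2L]])
  x <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  for (nm in names(config$bands)) {
    b <- config$bands[[nm]]
    gain <- exp(stats::rnorm(1, 0, config$subject_sd))
    part <- config$planted_partition[[nm]]
    comms <- sort(unique(part))
    latents <- vapply(comms, function(cc) bandlimited_noise(n, b$lo, b$hi, config$dt),
                      numeric(n))
    colnames(latents) <- as.character(comms)
    if (any(b$alpha > 0)) {
      alpha_c <- rep_len(b$alpha, length(comms))  # recycle scalar per community
      amp <- gain * alpha_c[match(part, comms)] * w
      x <- x + latents[, match(part, comms), drop = FALSE] *
        rep(amp, each = n)
    }
    if (b$beta > 0 && length(config$hub_rois)) {
      tg <- hub_targets(part, config$hub_rois)
      for (j in seq_along(config$hub_rois)) {
        i <- config$hub_rois[[j]]
        if (tg[[j]] != part[[i]]) {
          x[, i] <- x[, i] +
            gain * b$beta * w[[i]] * latents[, as.character(tg[[j]])]
        }
      }
    }
  }
  for (cf in config$confounds) {
    tt <- (seq_len(n) - 1L) * config$dt
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + cf$amplitude * sin(2 * pi * cf$freq * tt + phase)
  }
  colnames(x) <- sprintf("roi%03d", seq_len(p))
  ts_panel(x, dt = config$dt, subject_id = sprintf("sim%02d", s))
}

#' Ground truth planted by a generator config
#'
#' @param config a [generator_config()].
#' @return list of class `planted_structure` with per-band community labels
#'   (`partition`), per-band hub sets (`hubs`, ROIs with a positive bridge
#'   amplitude in that band), per-hub bridge targets (`targets`), and
#'   `coupling_order`, the band names sorted by decreasing community
#'   coupling strength (the expected ordering of intra-community coherence
#'   and of segregation among bands).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  hubs <- lapply(config$bands, function(b) {
    if (b$beta > 0) config$hub_rois else integer()
  })
  targets <- lapply(names(config$bands), function(nm) {
    hub_targets(config$planted_partition[[nm]], config$hub_rois)
  })
  names(targets) <- names(config$bands)
  alphas <- vapply(config$bands, function(b) mean(b$alpha), numeric(1))
  structure(list(partition = config$planted_partition,
                 hubs = hubs, targets = targets,
                 coupling_order = names(sort(alphas, decreasing = TRUE))),
            class = "planted_structure")
}
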