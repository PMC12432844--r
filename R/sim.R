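#' Configuration for the synthetic audience generator
#'
#' Defines the simulated study conditions: an audience of `n_subjects`
#' mobile-EEG wearers (32 channels at 250 Hz for tens of minutes), a shared
#' band-limited cortical source whose scalp projection is amplitude-modulated
#' by a slow engagement gain in `[0, 1]`, per-subject spatially correlated
#' noise, sparse large-amplitude artifact bursts, per-device clock offsets
#' with a blackout step in the photoresistor channel, and a 1 Hz feature
#' with a planted lagged influence on the shared gain.
#'
#' @param n_subjects number of subjects (>= 2; default 20).
#' @param n_channels channels per subject (default 32).
#' @param sample_rate Hz (default 250).
#' @param duration seconds (default 600).
#' @param band [band_spec()] of the shared source (default delta, 1-4 Hz).
#' @param snr shared-to-noise amplitude ratio (>= 0; default 1).
#' @param gain_profile optional function of time (seconds) returning the
#'   engagement gain in `[0, 1]`; default: smoothed random walk with ~180 s
#'   correlation length rescaled to `[0, 1]`.
#' @param artifact_rate artifact bursts per minute per subject (default 2).
#' @param artifact_scale burst amplitude in channel SDs (default 8).
#' @param coupling_lag lag (seconds) at which the coupled feature drives the
#'   gain (default 3).
#' @param coupling_beta coupling strength (default 1; 0 = no coupling).
#' @param device_offsets per-subject clock offsets in seconds (default:
#'   uniform in +/- 0.25 s, drawn from the seed).
#' @param blackout_time house-lights blackout time in seconds (default 12).
#' @param noise_corr inter-channel noise correlation (default 0.3,
#'   mimicking volume conduction).
#' @param seed single integer; every stochastic draw derives from it by
#'   fixed sub-stream indexing.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20L, n_channels = 32L, sample_rate = 250,
                       duration = 600, band = band_spec("delta", 1, 4),
                       snr = 1, gain_profile = NULL, artifact_rate = 2,
                       artifact_scale = 8, coupling_lag = 3,
                       coupling_beta = 1, device_offsets = NULL,
                       blackout_time = 12, noise_corr = 0.3, seed = 1L) {
  if (n_subjects < 2L) stop("invalid-config: need n_subjects >= 2")
  if (duration <= 0 || sample_rate <= 0)
    stop("invalid-config: duration and sample_rate must be positive")
  if (!(band$low > 0 && band$high > band$low && band$high < sample_rate / 2))
    stop("invalid-config: band must satisfy 0 < low < high < Nyquist")
  if (snr < 0) stop("invalid-config: snr must be >= 0")
  if (abs(duration * sample_rate - round(duration * sample_rate)) > 1e-8)
    stop("invalid-config: duration * sample_rate must be an integer")
  if (coupling_lag >= duration)
    stop("invalid-config: coupling_lag must be shorter than duration")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 sample_rate = sample_rate, duration = duration, band = band,
                 snr = snr, gain_profile = gain_profile,
                 artifact_rate = artifact_rate,
                 artifact_scale = artifact_scale,
                 coupling_lag = coupling_lag, coupling_beta = coupling_beta,
                 device_offsets = device_offsets,
                 blackout_time = blackout_time, noise_corr = noise_corr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Smoothed random walk at 1 Hz rescaled to [0, 1]; ~`corr_len` s correlation.
smooth_walk01 <- function(n_sec, corr_len = 180) {
  w <- cumsum(stats::rnorm(n_sec + 2 * corr_len))
  k <- stats::dnorm(seq(-2, 2, length.out = corr_len))
  k <- k / sum(k)
  s <- stats::filter(w, k, sides = 2)
  s <- s[corr_len + seq_len(n_sec)]
  s <- s - min(s)
  if (max(s) > 0) s <- s / max(s)
  as.numeric(s)
}

#' Simulate a multi-subject audience recording with known ground truth
#'
#' Each subject's channels x samples matrix is
#' `gain(t) * snr * m_k s(t) + noise + artifacts`, where `s(t)` is a shared
#' band-limited unit-variance source (white noise passed through the same
#' 5th-order Butterworth band-pass used in preprocessing), `m_k` a
#' per-subject unit-norm mixing vector, the noise is unit-variance with
#' inter-channel correlation `noise_corr`, and artifacts are 200 ms boxcar
#' bursts of `artifact_scale` channel SDs on a random channel subset. When
#' `coupling_beta > 0`, the gain's fast component is driven by a white 1 Hz
#' feature `f` delayed by `coupling_lag` seconds, so that
#' `gain(t) = scale(base(t) + coupling_beta * f(t - lag) + noise)`; `f` is
#' returned in the ground truth and by [simulate_features()].
#'
#' Device clock offsets shift each subject's recording relative to the master
#' clock; [simulate_photoresistor()] produces the matching blackout traces
#' that [align_recordings()] uses to undo them. Output is bit-identical for
#' a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `group` (a [group_recording()], `aligned = FALSE` when
#'   offsets are nonzero) and `truth` (source, gain at 1 Hz, mixing,
#'   planted_lag, coupled_feature, artifact_times, device_offsets).
#' @export
simulate_audience <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  N <- config$n_subjects; D <- config$n_channels
  n_sec <- round(config$duration)
  pad_s <- 2                                     # master-clock margin, seconds
  pad_n <- round(pad_s * fs)
  Tn <- round(config$duration * fs)
  Tm <- Tn + 2L * pad_n
  seed <- config$seed

  # shared band-limited source on the master clock
  src <- with_substream(seed, 1L, stats::rnorm(Tm))
  bf <- signal::butter(config$band$order,
                       c(config$band$low, config$band$high) / (fs / 2), "pass")
  src <- signal::filtfilt(bf, src)
  src <- src / stats::sd(src)

  # engagement gain at 1 Hz (master seconds), optionally feature-driven
  f <- with_substream(seed, 2L, stats::rnorm(n_sec + 2 * pad_s))
  base <- if (is.null(config$gain_profile)) {
    with_substream(seed, 3L, smooth_walk01(n_sec + 2 * pad_s))
  } else {
    config$gain_profile(seq_len(n_sec + 2 * pad_s) - 1 - pad_s)
  }
  eps <- with_substream(seed, 4L, stats::rnorm(n_sec + 2 * pad_s, sd = 0.3))
  lag <- round(config$coupling_lag)
  f_lag <- c(rep(0, lag), f)[seq_len(n_sec + 2 * pad_s)]
  if (!is.null(config$gain_profile) && config$coupling_beta == 0) {
    # a user-supplied profile with no coupling is honoured exactly
    gain_sec <- pmin(1, pmax(0, base))
  } else {
    base_std <- if (stats::sd(base) > 0) as.numeric(scale(base)) else base * 0
    raw <- base_std + config$coupling_beta * f_lag + eps
    gain_sec <- raw - min(raw)
    if (max(gain_sec) > 0) gain_sec <- gain_sec / max(gain_sec)
  }
  # per-sample gain by linear interpolation of the 1 Hz profile
  gain_full <- stats::approx(x = seq_along(gain_sec) - 1,
                             y = gain_sec,
                             xout = (seq_len(Tm) - 1) / fs, rule = 2)$y

  # mixing vectors: common topography plus per-subject jitter, unit norm
  m0 <- with_substream(seed, 5L, stats::rnorm(D))
  mixing <- with_substream(seed, 6L, {
    M <- m0 + 0.5 * matrix(stats::rnorm(D * N), D, N)
    apply(M, 2L, function(v) v / sqrt(sum(v^2)))
  })

  offsets <- config$device_offsets
  if (is.null(offsets))
    offsets <- with_substream(seed, 7L, stats::runif(N, -0.25, 0.25))
  if (length(offsets) != N) stop("invalid-config: need one offset per subject")
  if (any(abs(offsets) >= pad_s)) stop("invalid-config: |offset| must be < 2 s")

  Cn <- matrix(config$noise_corr, D, D); diag(Cn) <- 1
  Ln <- chol(Cn)
  labels <- paste0("Ch", seq_len(D))
  recs <- vector("list", N)
  artifact_times <- vector("list", N)
  shared <- t(mixing) # N x D
  for (k in seq_len(N)) {
    noise <- with_substream(seed, 100L + k,
                            t(Ln) %*% matrix(stats::rnorm(D * Tm), D, Tm))
    Xm <- config$snr * outer(mixing[, k], src * gain_full) + noise
    start <- pad_n + round(offsets[k] * fs)
    Xk <- Xm[, (start + 1L):(start + Tn), drop = FALSE]
    # artifact bursts: 200 ms boxcars on a random channel subset
    at <- numeric(0)
    n_art <- with_substream(seed, 200L + k,
                            stats::rpois(1, config$artifact_rate * config$duration / 60))
    if (n_art > 0 && config$artifact_scale > 0) {
      burst_n <- round(0.2 * fs)
      art <- with_substream(seed, 300L + k, {
        t0 <- sort(stats::runif(n_art, 0, config$duration - 0.2))
        chs <- lapply(seq_len(n_art), function(i)
          sample.int(D, size = max(1L, stats::rbinom(1, D, 0.2))))
        sgn <- sample(c(-1, 1), n_art, replace = TRUE)
        list(t0 = t0, chs = chs, sgn = sgn)
      })
      sds <- apply(Xk, 1L, stats::sd)
      for (i in seq_len(n_art)) {
        i0 <- round(art$t0[i] * fs) + 1L
        idx <- i0:min(Tn, i0 + burst_n - 1L)
        ch <- art$chs[[i]]
        Xk[ch, idx] <- Xk[ch, idx] +
          art$sgn[i] * config$artifact_scale * sds[ch]
      }
      at <- art$t0
    }
    artifact_times[[k]] <- at
    recs[[k]] <- recording(Xk, fs, channel_labels = labels,
                           subject_id = sprintf("S%02d", k))
  }
  group <- group_recording(recs, aligned = all(offsets == 0))
  truth <- list(source = src[(pad_n + 1L):(pad_n + Tn)],
                gain = gain_sec[pad_s + seq_len(n_sec)],
                mixing = mixing, planted_lag = lag,
                coupled_feature = f[pad_s + seq_len(n_sec)],
                artifact_times = artifact_times,
                device_offsets = offsets,
                blackout_time = config$blackout_time)
  list(group = group, truth = truth)
}

#' A 1 Hz feature series
#'
#' @param name feature label (e.g. `audio_rms`, `pulse_clarity`, `accel`,
#'   `distance`, `luminance`, `rating`, `respiration_sync`).
#' @param values numeric series.
#' @param rate sampling rate in Hz (canonical 1).
#' @param units unit label.
#' @return object of class `feature_series`.
#' @export
feature_series <- function(name, values, rate = 1, units = "") {
  structure(list(name = name, rate = rate, values = as.numeric(values),
                 units = units),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series %s: %d samples @ %g Hz>\n", x$name,
              length(x$values), x$rate))
  invisible(x)
}

#' @export
as.data.frame.feature_series <- function(x, ...) {
  data.frame(name = x$name, t_s = (seq_along(x$values) - 1) / x$rate,
             value = x$values)
}

#' Simulate 1 Hz performance-feature series
#'
#' Returns the coupled feature `f` that drives the simulated engagement gain
#' at `coupling_lag` seconds (white at 1 Hz, so the planted lag is
#' identifiable) plus `n_independent` independent AR(1) series with no
#' relation to the gain.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_audience()].
#' @param n_independent number of uncoupled series (default 1).
#' @param seed optional seed for the independent series (default
#'   `config$seed`).
#' @return named list of [feature_series()]; the coupled series is named
#'   `"coupled"`, the rest `"independent1"`, ...
#' @export
simulate_features <- function(config, truth, n_independent = 1L,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coupling_lag >= config$duration)
    stop("invalid-config: coupling_lag must be shorter than duration")
  n_sec <- length(truth$gain)
  out <- list(coupled = feature_series("coupled", truth$coupled_feature))
  for (j in seq_len(n_independent)) {
    x <- with_substream(seed, 400L + j,
                        as.numeric(stats::arima.sim(list(ar = 0.6), n_sec)))
    out[[paste0("independent", j)]] <-
      feature_series(paste0("independent", j), x)
  }
  out
}

#' Simulate per-device photoresistor traces
#'
#' Each subject's trace sits at a high light level and ramps linearly to a
#' low level over 0.5 s when the house lights black out; the blackout
#' appears at `blackout_time` shifted by that device's clock offset, plus
#' measurement noise.
#'
#' @param config a [sim_config()].
#' @param noise_sd measurement noise SD (default 0.02; 0 for noise-free).
#' @return list of numeric traces (one per subject) at `sample_rate`.
#' @export
simulate_photoresistor <- function(config, noise_sd = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  Tn <- round(config$duration * fs)
  offsets <- config$device_offsets
  if (is.null(offsets))
    offsets <- with_substream(config$seed, 7L,
                              stats::runif(config$n_subjects, -0.25, 0.25))
  lapply(seq_len(config$n_subjects), function(k) {
    t_on <- config$blackout_time - offsets[k]
    tt <- (seq_len(Tn) - 1) / fs
    ramp <- pmin(1, pmax(0, (tt - t_on) / 0.5))
    tr <- 1 - 0.95 * ramp
    if (noise_sd > 0)
      tr <- tr + with_substream(config$seed, 500L + k,
                                stats::rnorm(Tn, sd = noise_sd))
    tr
  })
}

#' Simulate respiration-belt traces sharing a slow common rhythm
#'
#' A common ~0.25 Hz breathing oscillation with per-subject amplitude, phase
#' jitter, baseline drift, and sensor noise, sampled at 500 Hz for input to
#' [clean_respiration()].
#'
#' @param config a [sim_config()].
#' @param rate output rate in Hz (default 500).
#' @param shared fraction of the rhythm shared across subjects (0-1,
#'   default 0.7).
#' @return list of numeric traces (one per subject).
#' @export
simulate_respiration <- function(config, rate = 500, shared = 0.7) {
  stopifnot(inherits(config, "sim_config"))
  Tn <- round(config$duration * rate)
  tt <- (seq_len(Tn) - 1) / rate
  common <- sin(2 * pi * 0.25 * tt)
  lapply(seq_len(config$n_subjects), function(k) {
    with_substream(config$seed, 600L + k, {
      phi <- stats::runif(1, -0.3, 0.3)
      own <- sin(2 * pi * stats::runif(1, 0.2, 0.3) * tt + phi)
      drift <- cumsum(stats::rnorm(Tn, sd = 0.001))
      shared * common + (1 - shared) * own + drift +
        stats::rnorm(Tn, sd = 0.1)
    })
  })
}
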