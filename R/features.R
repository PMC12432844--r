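# 1 Hz canonicalization: linear interpolation onto a fine uniform grid, then
# block averaging per second. `times` are sample times in seconds.
to_1hz <- function(values, times, duration = NULL, fine = 20) {
  ok <- is.finite(values) & is.finite(times)
  values <- values[ok]; times <- times[ok]
  if (length(values) < 2L) stop("need at least 2 samples")
  if (is.null(duration)) duration <- floor(max(times)) + 1
  tg <- seq(0, duration - 1 / fine, by = 1 / fine)
  vi <- stats::approx(times, values, xout = tg, rule = 2)$y
  as.numeric(tapply(vi, floor(tg), mean))
}

#' Root-mean-square audio energy
#'
#' RMS amplitude over 50 ms windows with 50% overlap (25 ms hop), then
#' canonicalized to 1 Hz. An index of perceived loudness.
#'
#' @param audio mono numeric vector.
#' @param rate audio sampling rate in Hz (>= 8000).
#' @return a [feature_series()] named `audio_rms` at 1 Hz.
#' @export
rms_energy <- function(audio, rate) {
  if (length(audio) == 0L) stop("empty audio")
  if (rate < 8000) stop("audio rate must be >= 8 kHz")
  win <- round(0.050 * rate); hop <- round(0.025 * rate)
  starts <- seq(1L, length(audio) - win + 1L, by = hop)
  cs <- c(0, cumsum(audio^2))
  r <- sqrt((cs[starts + win] - cs[starts]) / win)
  tt <- (starts - 1 + win / 2) / rate
  feature_series("audio_rms", to_1hz(r, tt, duration = floor(length(audio) / rate)))
}

#' Pulse clarity (beat-strength index)
#'
#' A simplified autocorrelation beat-strength index, not a re-implementation
#' of the MIRtoolbox estimator: per 5 s window (10% overlap, 4.5 s hop) an
#' onset envelope (half-wave-rectified derivative of 10 ms frame energy) is
#' autocorrelated, and clarity is the largest autocorrelation peak in the
#' 40-200 beats/min lag range (0.3-1.5 s), normalized by lag zero and
#' clipped to `[0, 1]`.
#'
#' @param audio mono numeric vector.
#' @param rate audio sampling rate in Hz.
#' @return a [feature_series()] named `pulse_clarity` at 1 Hz.
#' @export
pulse_clarity <- function(audio, rate) {
  if (length(audio) == 0L) stop("empty audio")
  frame <- round(0.010 * rate)
  n_fr <- floor(length(audio) / frame)
  env <- sqrt(colMeans(matrix(audio[seq_len(n_fr * frame)]^2, frame)))
  env_rate <- rate / frame                       # 100 Hz
  onset <- pmax(diff(env), 0)
  win <- round(5 * env_rate); hop <- round(4.5 * env_rate)
  if (length(onset) < win) stop("audio shorter than one 5 s window")
  starts <- seq(1L, length(onset) - win + 1L, by = hop)
  lag_lo <- round(0.3 * env_rate); lag_hi <- round(1.5 * env_rate)
  vals <- vapply(starts, function(s) {
    seg <- onset[s:(s + win - 1L)]
    seg <- seg - mean(seg)
    if (sum(seg^2) == 0) return(0)
    ac <- stats::acf(seg, lag.max = lag_hi, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    peak <- max(ac[(lag_lo + 1L):(lag_hi + 1L)])
    min(1, max(0, peak))
  }, numeric(1))
  tt <- (starts - 1 + win / 2) / env_rate
  feature_series("pulse_clarity",
                 to_1hz(vals, tt, duration = floor(length(audio) / rate)))
}

#' Combined movement acceleration of the performers
#'
#' Per wrist sensor, the x/y/z acceleration is resampled to a uniform 20 Hz
#' clock (0.05 s steps, linear interpolation) and reduced to the root summed
#' square `sqrt(x^2 + y^2 + z^2)`; the combined series is the median across
#' performers (equal to the mean for two), canonicalized to 1 Hz.
#'
#' @param wrists list of per-wrist lists with `t` (seconds) and `x`, `y`,
#'   `z` numeric vectors.
#' @return a [feature_series()] named `accel` at 1 Hz, with attribute
#'   `"interpolation_flagged"` when any gap exceeds 1 s.
#' @export
accel_magnitude <- function(wrists) {
  stopifnot(length(wrists) >= 1L)
  dur <- floor(min(vapply(wrists, function(w) max(w$t), numeric(1)))) + 1
  tg <- seq(0, dur - 0.05, by = 0.05)
  flagged <- FALSE
  mags <- lapply(wrists, function(w) {
    if (any(diff(sort(w$t)) > 1)) flagged <<- TRUE
    xi <- stats::approx(w$t, w$x, xout = tg, rule = 2)$y
    yi <- stats::approx(w$t, w$y, xout = tg, rule = 2)$y
    zi <- stats::approx(w$t, w$z, xout = tg, rule = 2)$y
    sqrt(xi^2 + yi^2 + zi^2)
  })
  comb <- apply(do.call(cbind, mags), 1L, stats::median)
  out <- feature_series("accel", to_1hz(comb, tg, duration = dur),
                        units = "m/s^2")
  attr(out, "interpolation_flagged") <- flagged
  out
}

#' Distance between two performers on stage
#'
#' Euclidean distance per frame from 2-D stage positions; missing
#' coordinates are linearly interpolated when the gap is at most 2 s (longer
#' gaps stay missing), then the distance is averaged over 5 s windows with
#' 80% overlap, landing on the 1 Hz grid.
#'
#' @param posA,posB lists with `t` (seconds) and `x`, `y` coordinates on
#'   common timestamps.
#' @return a [feature_series()] named `distance` at 1 Hz.
#' @export
pair_distance <- function(posA, posB) {
  if (!isTRUE(all.equal(posA$t, posB$t))) stop("positions need common timestamps")
  tt <- posA$t
  fill <- function(v) {
    bad <- !is.finite(v)
    if (!any(bad)) return(v)
    out <- stats::approx(tt[!bad], v[!bad], xout = tt, rule = 2)$y
    # re-blank gaps longer than 2 s
    r <- rle(bad)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (tt[ends[j]] - tt[starts[j]] > 2) out[starts[j]:ends[j]] <- NA
    }
    out
  }
  d <- sqrt((fill(posA$x) - fill(posB$x))^2 + (fill(posA$y) - fill(posB$y))^2)
  dur <- floor(max(tt)) + 1
  ok <- is.finite(d)
  wg <- window_grid(max(5, floor(dur)), length = 5, hop = 1)
  vals <- vapply(wg$starts, function(s) {
    sel <- tt >= s & tt < s + 5 & ok
    if (!any(sel)) NA_real_ else mean(d[sel])
  }, numeric(1))
  feature_series("distance", to_1hz(vals, wg$starts + 2.5, duration = dur),
                 units = "m")
}

#' Luminance feature from per-frame mean gray values
#'
#' Video decoding is out of scope; this takes one mean-luminance value per
#' frame and canonicalizes to 1 Hz.
#'
#' @param frames numeric vector, one mean-gray value per frame.
#' @param fps frames per second (> 0).
#' @return a [feature_series()] named `luminance` at 1 Hz.
#' @export
luminance_series <- function(frames, fps) {
  if (fps <= 0) stop("fps must be positive")
  tt <- (seq_along(frames) - 1) / fps
  feature_series("luminance",
                 to_1hz(frames, tt, duration = floor(length(frames) / fps)))
}

#' Centered rolling median
#'
#' Rolling median with a centered window; at the edges the window shrinks
#' symmetrically. Used to smooth rating and synchrony series (e.g. 180 s for
#' rating agreement, 60 s for display).
#'
#' @param x numeric series.
#' @param window window span in seconds.
#' @param rate series rate in Hz (default 1).
#' @return smoothed series, same length.
#' @export
rolling_median <- function(x, window, rate = 1) {
  n <- length(x)
  h <- floor(window * rate / 2)
  if (2 * h + 1 > n) stop("window exceeds the series span")
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    stats::median(x[(i - hh):(i + hh)], na.rm = TRUE)
  }, numeric(1))
}

#' Window a continuous rating series onto the analysis grid
#'
#' Mean rating per 5 s window with 80% overlap (1 s hop) -- the same grid as
#' the time-resolved synchrony, so ratings can enter the coupling analysis
#' directly.
#'
#' @param series numeric rating series.
#' @param rate rating sampling rate in Hz (>= 1).
#' @param length,overlap window parameters (default 5 s, 0.8).
#' @return a [feature_series()] named `rating` on the window grid (1 Hz for
#'   the defaults).
#' @export
window_ratings <- function(series, rate, length = 5, overlap = 0.8) {
  if (rate < 1) stop("rating must be sampled at >= 1 Hz")
  hop <- length * (1 - overlap)
  dur <- base::length(series) / rate
  wg <- window_grid(dur, length = length, hop = hop)
  gs <- grid_samples(wg, rate)
  vals <- wsum(series, gs$start, gs$len) / gs$len
  feature_series("rating", vals, rate = 1 / hop)
}

#' Respiration synchrony of the audience
#'
#' The single-channel degenerate case of the correlated-components method:
#' per window, the summed between-subject covariance over `(N - 1)` times
#' the summed within-subject variance -- i.e. a between-subject mean
#' pairwise correlation under the same normalization as the EEG ISC, on the
#' same grid.
#'
#' @param traces list of cleaned, aligned respiration traces (equal length).
#' @param rate trace rate in Hz (250 after [clean_respiration()]).
#' @param grid a [window_grid()]; default the canonical 5 s / 1 s grid.
#' @return an `isc_series` (band `"respiration"`).
#' @export
respiration_synchrony <- function(traces, rate = 250, grid = NULL) {
  if (length(traces) < 2L) stop("need at least 2 respiration traces")
  recs <- lapply(seq_along(traces), function(k)
    recording(matrix(traces[[k]], 1L), rate, channel_labels = "RESP",
              subject_id = sprintf("S%02d", k)))
  group <- group_recording(recs, aligned = TRUE)
  if (is.null(grid)) grid <- window_grid(rec_duration(recs[[1]]))
  model <- structure(list(weights = matrix(1, 1, 1), forward = matrix(1, 1, 1),
                          isc = NA_real_, isc_all = NA_real_, Rw = NULL,
                          Rb = NULL, n_subjects = length(traces), lambda = 0),
                     class = "cca_model")
  out <- isc_timecourse(group, model, grid, components = 1L)
  out$band <- "respiration"
  out
}

#' Spectral centroid of a feature series
#'
#' First moment of the periodogram (mean removed); reported so the spectral
#' content of each feature can be compared against the EEG analysis bands.
#'
#' @param feat a [feature_series()].
#' @return centroid frequency in Hz.
#' @export
spectral_centroid <- function(feat) {
  x <- feat$values - mean(feat$values)
  sp <- stats::spec.pgram(stats::ts(x, frequency = feat$rate), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$freq * sp$spec) / sum(sp$spec)
}
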