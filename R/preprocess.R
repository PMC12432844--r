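#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel with a Butterworth band-pass applied forward and
#' backward (`signal::filtfilt`), so the output is zero-phase. Zero-phase
#' filtering is used because the downstream correlated-components and
#' phase-locking statistics are phase-sensitive; the effective order doubling
#' is accepted.
#'
#' @param rec a [recording()].
#' @param band a [band_spec()].
#' @return the filtered recording, with `$band` set.
#' @export
bandpass_filter <- function(rec, band) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  nyq <- rec$sample_rate / 2
  if (band$high >= nyq)
    stop(sprintf("invalid band: high edge %g Hz >= Nyquist %g Hz",
                 band$high, nyq))
  bf <- signal::butter(band$order, c(band$low, band$high) / nyq, type = "pass")
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, function(ch) signal::filtfilt(bf, ch)))
  rownames(out$samples) <- rec$channel_labels
  out$band <- band
  out
}

#' Optional broadband high-pass / low-pass filters
#'
#' Zero-phase Butterworth high- or low-pass, available for broadband cleaning
#' ahead of band-specific analysis.
#'
#' @param rec a [recording()].
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @return filtered recording.
#' @export
highpass_filter <- function(rec, cutoff, order = 5L) {
  nyq <- rec$sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  rec$samples <- t(apply(rec$samples, 1L, function(ch) signal::filtfilt(bf, ch)))
  rownames(rec$samples) <- rec$channel_labels
  rec
}

#' @rdname highpass_filter
#' @export
lowpass_filter <- function(rec, cutoff, order = 5L) {
  nyq <- rec$sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) stop("cutoff must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  rec$samples <- t(apply(rec$samples, 1L, function(ch) signal::filtfilt(bf, ch)))
  rownames(rec$samples) <- rec$channel_labels
  rec
}

#' Zero out large-amplitude outlier samples
#'
#' Per channel, samples deviating from the channel mean by more than
#' `sd_threshold` standard deviations -- both computed over the channel's
#' currently unmasked samples -- are set to zero together with `pad` seconds
#' on each side, and flagged in the mask. The fraction of newly zeroed
#' samples is attached as attribute `"fraction_zeroed"`.
#'
#' A constant channel (zero SD) is left untouched with a warning.
#'
#' @param rec a [recording()].
#' @param sd_threshold SD multiple defining an outlier (default 4).
#' @param pad guard interval zeroed on each side of an outlier, seconds
#'   (default 0.040).
#' @return recording with outliers zeroed and mask updated.
#' @export
zero_outliers <- function(rec, sd_threshold = 4, pad = 0.040) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$samples)
  if (n < 1L) stop("recording has no samples")
  pad_n <- round(pad * rec$sample_rate)
  new_frac <- 0
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    keep <- !rec$mask[ch, ]
    mu <- mean(x[keep])
    sdv <- stats::sd(x[keep])
    if (!is.finite(sdv) || sdv == 0) {
      warning(sprintf("channel %s is constant; no outliers flagged",
                      rec$channel_labels[ch]))
      next
    }
    hit <- which(keep & abs(x - mu) > sd_threshold * sdv)
    if (length(hit) == 0L) next
    idx <- unique(unlist(lapply(hit, function(i)
      max(1L, i - pad_n):min(n, i + pad_n))))
    idx <- idx[!rec$mask[ch, idx]]
    rec$samples[ch, idx] <- 0
    rec$mask[ch, idx] <- TRUE
    new_frac <- new_frac + length(idx)
  }
  rec$has_mask <- any(rec$mask)
  attr(rec, "fraction_zeroed") <- new_frac / (nrow(rec$samples) * n)
  rec
}

#' Common average reference
#'
#' Subtracts the across-channel mean at every sample, so channel sums are
#' zero at each time point.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @return re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 2L) stop("common average reference needs >= 2 channels")
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples))
  rec
}

#' Downsample a recording
#'
#' Anti-aliased polyphase resampling (`signal::resample`) to a lower rate;
#' the target must divide into the rational ratio target/rate. Upsampling is
#' refused (the pipeline only downsamples, e.g. 500 -> 250 Hz).
#'
#' @param rec a [recording()].
#' @param target target rate in Hz.
#' @return resampled recording (mask is carried over by decimation of the
#'   validity pattern).
#' @export
resample_recording <- function(rec, target) {
  stopifnot(inherits(rec, "recording"))
  if (target > rec$sample_rate) stop("upsampling is not supported")
  if (target == rec$sample_rate) return(rec)
  r <- target / rec$sample_rate
  n_new <- round(ncol(rec$samples) * r)
  new <- t(apply(rec$samples, 1L, downsample_series,
                 rate = rec$sample_rate, target = target))
  old_idx <- pmin(ncol(rec$samples), floor((seq_len(n_new) - 1) / r) + 1L)
  out <- rec
  out$samples <- new
  rownames(out$samples) <- rec$channel_labels
  out$mask <- rec$mask[, old_idx, drop = FALSE]
  out$has_mask <- any(out$mask)
  out$sample_rate <- target
  out
}

# Zero-phase anti-aliased downsampling: forward-backward Butterworth low-pass
# at 0.45 * target rate, then interpolation onto the target grid. Zero phase
# keeps downstream phase-sensitive statistics honest; no warm-up transient
# delay like a one-sided FIR polyphase stage.
downsample_series <- function(x, rate, target) {
  bf <- signal::butter(8, (0.45 * target) / (rate / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  n_new <- round(length(x) * target / rate)
  t_new <- (seq_len(n_new) - 1) / target
  stats::approx((seq_along(x) - 1) / rate, xf, xout = t_new, rule = 2)$y
}

#' Clean a respiration-belt trace
#'
#' Downsamples to 250 Hz, replaces outliers relative to a 0.5 s moving median
#' with the average of the surrounding samples, then smooths with a 1 s
#' Savitzky-Golay filter (polynomial order 3).
#'
#' Outliers are samples whose deviation from the rolling median exceeds
#' `threshold` times a robust (MAD-based) SD of those deviations.
#'
#' @param trace numeric vector.
#' @param rate input rate in Hz (must be >= 250).
#' @param threshold robust-SD multiple defining an outlier (default 4).
#' @return cleaned series at 250 Hz.
#' @export
clean_respiration <- function(trace, rate, threshold = 4) {
  if (rate < 250) stop("respiration input rate must be >= 250 Hz")
  if (length(trace) < rate) stop("trace shorter than 1 s")
  if (rate > 250) trace <- downsample_series(trace, rate, 250)
  fs <- 250
  k <- round(0.5 * fs); if (k %% 2 == 0) k <- k + 1L
  med <- stats::runmed(trace, k, endrule = "median")
  dev <- trace - med
  s <- stats::mad(dev)
  if (s > 0) {
    bad <- which(abs(dev) > threshold * s)
    if (length(bad)) {
      good <- setdiff(seq_along(trace), bad)
      # replace each outlier with the mean of its nearest good neighbours
      lo <- findInterval(bad, good)
      prev <- good[pmax(lo, 1L)]
      nxt <- good[pmin(lo + 1L, length(good))]
      trace[bad] <- (trace[prev] + trace[nxt]) / 2
    }
  }
  w <- round(fs); if (w %% 2 == 0) w <- w + 1L
  signal::sgolayfilt(trace, p = 3, n = w)
}
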