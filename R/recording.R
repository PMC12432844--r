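#' Single-subject recording container
#'
#' The atomic EEG-like container: a channels x samples matrix with a sampling
#' rate, channel labels, and a logical mask marking samples that were zeroed
#' as outliers (same shape as the data; `TRUE` = zeroed).
#'
#' @param samples numeric matrix, channels x samples (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per channel (10/10
#'   convention for EEG; defaults to `Ch1..ChD`).
#' @param subject_id subject label.
#' @param mask optional logical matrix, same shape as `samples`.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sample_rate, channel_labels = NULL,
                      subject_id = "S1", mask = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric channels x samples matrix")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  d <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(d))
  if (length(channel_labels) != d)
    stop("channel_labels length must equal the number of channels")
  if (is.null(mask)) {
    mask <- matrix(FALSE, d, ncol(samples))
  } else if (!is.logical(mask) || !identical(dim(mask), dim(samples))) {
    stop("mask must be a logical matrix with the same shape as samples")
  }
  rownames(samples) <- channel_labels
  structure(
    list(subject_id = subject_id, channel_labels = channel_labels,
         sample_rate = sample_rate, samples = samples, mask = mask,
         band = NULL, has_mask = any(mask)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %d ch x %d samples @ %g Hz%s>\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$sample_rate,
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$sample_rate

#' Multi-subject recording stack
#'
#' Aligned multi-subject container: a list of [recording()] objects sharing
#' sample rate, channel set, and length. Input to all synchrony computations.
#'
#' @param recordings list of `recording` objects.
#' @param aligned logical; whether the recordings have been through (or do not
#'   need) temporal alignment.
#' @return an object of class `group_recording`.
#' @export
group_recording <- function(recordings, aligned = FALSE) {
  if (length(recordings) < 2L) stop("need at least 2 subjects")
  if (!all(vapply(recordings, inherits, logical(1), "recording")))
    stop("all elements must be recording objects")
  rates <- vapply(recordings, function(r) r$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) stop("sample rates differ across subjects")
  ns <- vapply(recordings, function(r) ncol(r$samples), numeric(1))
  if (length(unique(ns)) != 1L) stop("recording lengths differ across subjects")
  labs <- lapply(recordings, function(r) r$channel_labels)
  if (length(unique(labs)) != 1L)
    stop("channel labels must be identical across subjects")
  structure(list(recordings = recordings, sample_rate = rates[1],
                 aligned = aligned),
            class = "group_recording")
}

#' @export
print.group_recording <- function(x, ...) {
  r <- x$recordings[[1]]
  cat(sprintf("<group_recording: %d subjects, %d ch x %d samples @ %g Hz%s>\n",
              length(x$recordings), nrow(r$samples), ncol(r$samples),
              x$sample_rate, if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Number of subjects in a group recording
#' @param group a `group_recording`.
#' @return integer count.
#' @export
n_subjects <- function(group) length(group$recordings)

#' Apply a per-recording transform across a group
#' @param group a `group_recording`.
#' @param f function taking and returning a `recording`.
#' @param ... passed to `f`.
#' @return transformed `group_recording`.
#' @export
group_map <- function(group, f, ...) {
  group$recordings <- lapply(group$recordings, f, ...)
  group_recording(group$recordings, aligned = group$aligned)
}

# Per-sample validity: a sample is usable for cross-subject statistics only
# if no channel was zeroed there (artifact zeros are not data).
sample_valid <- function(rec) colSums(rec$mask) == 0L

# Cached "any sample masked" flag; recording() and zero_outliers() maintain
# it, and the hot surrogate loop relies on it to skip mask bookkeeping.
has_mask <- function(rec) {
  if (!is.null(rec$has_mask)) rec$has_mask else any(rec$mask)
}

#' Frequency band specification
#'
#' Canonical EEG analysis bands: delta 1-4, theta 4-8, alpha 8-12,
#' beta 12-20 Hz, filtered with a 5th-order Butterworth band-pass.
#'
#' @param name band label.
#' @param low,high band edges in Hz.
#' @param order Butterworth filter order.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(name, low, high, order = 5L) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low))
    stop("need 0 < low < high")
  structure(list(name = name, low = low, high = high, order = as.integer(order)),
            class = "band_spec")
}

#' Canonical frequency bands
#' @return named list of [band_spec()] objects (delta, theta, alpha, beta).
#' @export
canonical_bands <- function() {
  list(delta = band_spec("delta", 1, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 12),
       beta  = band_spec("beta", 12, 20))
}

# Derive a reproducible sub-stream seed from one global integer seed.
# Keeps results < 2^31 and distinct across (seed, stream) pairs.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 1e6) * 2048 + (as.numeric(stream) %% 2048)
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded by derive_seed(seed, stream),
# restoring the caller's RNG afterwards.
with_substream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}
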