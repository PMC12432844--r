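#' Detect the first blackout onset in a photoresistor trace
#'
#' Multi-device recordings are aligned on the house-lights blackout at the
#' start of the performance: each device carries a photoresistor whose signal
#' ramps from high to low when the lights go out. The onset is found as the
#' earliest change in slope: every candidate breakpoint splits the trace into
#' two segments, each fitted by least squares with its own line, and the
#' total residual is compared with the single-line fit. Candidates are first
#' localized coarsely as the earliest sliding window whose fitted slope
#' departs from the typical slope, then refined to the breakpoint minimizing
#' the two-segment residual; the detection is accepted only when the
#' relative residual reduction over the single line exceeds `threshold`.
#'
#' @param trace numeric photoresistor series.
#' @param rate sampling rate in Hz.
#' @param threshold minimum relative residual reduction (default 0.2) for a
#'   breakpoint to count as a change point.
#' @param window fit window on each side of a candidate breakpoint, seconds
#'   (default 0.4; keep it shorter than the blackout ramp).
#' @return list with `time` (seconds, 0-based), `index` (sample), `kind`
#'   ("slope-change"), and `score` (relative residual reduction); class
#'   `change_point`.
#' @export
detect_light_onset <- function(trace, rate, threshold = 0.2, window = 0.4) {
  n <- length(trace)
  if (n < 10 * rate) stop("trace must be at least 10 s long")
  x <- (seq_len(n) - 1) / rate
  y <- trace
  w <- round(window * rate)
  # interval regression sums via prefix sums: SSE of the best single line
  # over any sample range [i, j]
  cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(x * x)); cxy <- c(0, cumsum(x * y))
  cyy <- c(0, cumsum(y * y))
  seg_sse <- function(i, j) {
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    syy <- cyy[j + 1] - cyy[i]
    vx <- sxx - sx^2 / m
    vy <- syy - sy^2 / m
    vxy <- sxy - sx * sy / m
    pmax(0, vy - ifelse(vx > 0, vxy^2 / vx, 0))
  }
  seg_slope <- function(i, j) {
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    (sxy - sx * sy / m) / (sxx - sx^2 / m)
  }
  # coarse localization: the earliest sliding window whose fitted slope
  # departs from the typical slope by at least half the maximal departure
  bs <- seq.int(1L, n - w)
  sl <- seg_slope(bs, bs + w)
  dev <- abs(sl - stats::median(sl))
  if (max(dev) == 0)
    stop("no-change-point: no breakpoint reduces the residual by the threshold")
  t_star <- bs[which(dev >= 0.5 * max(dev))[1]]
  # refinement: breakpoint minimizing the total residual of two independent
  # line fits over its +/- window neighbourhood
  bc <- seq.int(max(w + 1L, t_star), min(n - w, t_star + w))
  sse2 <- seg_sse(bc - w, bc) + seg_sse(bc + 1L, bc + w)
  i <- bc[which.min(sse2)]
  sse1 <- seg_sse(i - w, i + w)
  score <- if (sse1 > 0) 1 - min(sse2) / sse1 else 0
  if (score < threshold)
    stop("no-change-point: no breakpoint reduces the residual by the threshold")
  # sub-sample polish: fit a line well into each segment (a guard band around
  # the break excluded) and place the onset at their intersection
  seg_line <- function(i, j) {
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    sxx <- cxx[j + 1] - cxx[i]; sxy <- cxy[j + 1] - cxy[i]
    sl <- (sxy - sx * sy / m) / (sxx - sx^2 / m)
    c(slope = sl, intercept = sy / m - sl * sx / m)
  }
  g <- max(2L, round(0.02 * rate))
  lw <- max(1L, i - round(2 * rate))
  left <- seg_line(lw, max(lw + 4L, i - g))
  right <- seg_line(i + g, i + w)
  t_hat <- (i - 1) / rate
  if (is.finite(left[1]) && is.finite(right[1]) &&
      abs(right[1] - left[1]) > 1e-12) {
    t_x <- (left[2] - right[2]) / (right[1] - left[1])
    if (abs(t_x - t_hat) <= window) t_hat <- t_x
  }
  structure(list(time = t_hat, index = round(t_hat * rate) + 1L,
                 kind = "slope-change", score = score),
            class = "change_point")
}

#' Align a group of recordings on per-device blackout onsets
#'
#' The reference is the subject whose onset minimizes the summed absolute
#' onset difference to all others. Every recording is shifted by
#' (reference onset - own onset) and all recordings are trimmed to the
#' jointly observed span, so windowed statistics only ever see time observed
#' by every device.
#'
#' @param group a [group_recording()].
#' @param onsets list of [detect_light_onset()] results (or numeric onset
#'   times in seconds), one per subject.
#' @param max_shift_frac maximum plausible shift as a fraction of the
#'   recording duration (default 0.1); larger shifts raise an error.
#' @return aligned `group_recording` with attribute `"offsets"` (applied
#'   shifts, seconds).
#' @export
align_recordings <- function(group, onsets, max_shift_frac = 0.1) {
  stopifnot(inherits(group, "group_recording"))
  N <- n_subjects(group)
  t_on <- vapply(onsets, function(o) if (inherits(o, "change_point")) o$time
                 else as.numeric(o), numeric(1))
  if (length(t_on) != N) stop("need one onset per subject")
  fs <- group$sample_rate
  ref <- which.min(rowSums(abs(outer(t_on, t_on, "-"))))
  shift_s <- t_on - t_on[ref]           # how much earlier each device started
  dur <- rec_duration(group$recordings[[1]])
  if (any(abs(shift_s) > max_shift_frac * dur))
    stop("suspicious-offset: shift exceeds 10% of the recording duration")
  i_on <- round(t_on * fs) + 1L
  n <- ncol(group$recordings[[1]]$samples)
  lead <- min(i_on) - 1L                # samples available before every onset
  trail <- min(n - i_on)                # samples available after every onset
  recs <- vector("list", N)
  for (k in seq_len(N)) {
    sel <- (i_on[k] - lead):(i_on[k] + trail)
    r <- group$recordings[[k]]
    r$samples <- r$samples[, sel, drop = FALSE]
    r$mask <- r$mask[, sel, drop = FALSE]
    recs[[k]] <- r
  }
  out <- group_recording(recs, aligned = TRUE)
  attr(out, "offsets") <- -shift_s
  out
}
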