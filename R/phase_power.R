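# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Unwrap a phase series
#'
#' Removes 2*pi discontinuities so the phase advances continuously.
#'
#' @param theta phase vector in radians.
#' @return unwrapped phase.
#' @export
unwrap_phase <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(theta[1], theta[1] + cumsum(d))
}

#' Instantaneous phase of band-passed channels
#'
#' Applies the Hilbert transform to extract the analytic signal per channel
#' and takes its angle: the instantaneous phase in `(-pi, pi]`. Meaningful
#' only on narrowband (band-passed) input; a recording that has not been
#' through [bandpass_filter()] triggers a warning.
#'
#' @param rec a band-passed [recording()].
#' @return numeric matrix of phases (channels x samples, radians) with
#'   attributes `rate` and `channel_labels`.
#' @export
instantaneous_phase <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$band))
    warning("input has no band annotation; phase of broadband data is ill-defined")
  ph <- t(apply(rec$samples, 1L, function(ch) Arg(analytic_signal(ch))))
  rownames(ph) <- rec$channel_labels
  attr(ph, "rate") <- rec$sample_rate
  ph
}

#' Windowed phase-locking value between two phase series
#'
#' Per window, `PLV = | (1/T) sum_t exp(i (theta_j(t) - theta_k(t))) |`:
#' the modulus of the mean unit phasor of the phase difference. 1 means
#' perfect phase locking (including any constant phase offset), 0 none;
#' phase differences that sweep a full cycle uniformly (complete roots of
#' unity) give exactly 0. Defaults: 5 s windows with 4 s overlap (1 s hop).
#'
#' @param theta_j,theta_k phase vectors (radians), equal length.
#' @param rate sampling rate in Hz.
#' @param length,hop window parameters in seconds (default 5 and 1).
#' @param valid optional logical vector; windows with more than 50% invalid
#'   samples yield `NA`.
#' @return list with `plv` (per window), `grid` (a [window_grid()]), and
#'   `T` (samples per window).
#' @export
plv_pairwise <- function(theta_j, theta_k, rate, length = 5, hop = 1,
                         valid = NULL) {
  n <- base::length(theta_j)
  if (base::length(theta_k) != n) stop("phase series lengths differ")
  grid <- window_grid(n / rate, length = length, hop = hop)
  gs <- grid_samples(grid, rate)
  z <- exp(1i * (theta_j - theta_k))
  if (!is.null(valid)) z[!valid] <- 0i
  re <- wsum(Re(z), gs$start, gs$len)
  im <- wsum(Im(z), gs$start, gs$len)
  Tn <- if (is.null(valid)) rep(gs$len, grid$n_windows)
        else wsum(valid, gs$start, gs$len)
  plv <- sqrt(re^2 + im^2) / Tn
  plv[Tn < gs$len / 2] <- NA_real_
  list(plv = plv, grid = grid, T = Tn)
}

#' Phase-locking values for labelled performance sections
#'
#' Computes delta-band PLV for every subject pair at the requested analysis
#' electrodes (default the central set C3, C4, Cz and occipital set O1, Oz,
#' O2), restricted to windows inside each labelled section. For N subjects
#' there are `choose(N, 2)` pairs (e.g. 190, 153, 210 for N = 20, 18, 21).
#'
#' @param group band-passed, aligned [group_recording()].
#' @param sections data frame with `label`, `start`, `end` (seconds).
#' @param electrodes electrode labels to analyse (must exist in the group).
#' @param non_overlapping use back-to-back 5 s windows (36 per 3 min)
#'   instead of the default 1 s hop.
#' @return data frame: section, subj_j, subj_k, electrode, region,
#'   window_start_s, plv, T.
#' @export
section_plv <- function(group, sections,
                        electrodes = c("C3", "C4", "Cz", "O1", "Oz", "O2"),
                        non_overlapping = FALSE) {
  stopifnot(inherits(group, "group_recording"))
  labs <- group$recordings[[1]]$channel_labels
  missing_el <- setdiff(electrodes, labs)
  if (length(missing_el))
    stop("unknown electrode(s): ", paste(missing_el, collapse = ", "))
  region <- ifelse(startsWith(electrodes, "C"), "central", "occipital")
  names(region) <- electrodes
  fs <- group$sample_rate
  hop <- if (non_overlapping) 5 else 1
  N <- n_subjects(group)
  phases <- lapply(group$recordings, instantaneous_phase)
  valid <- lapply(group$recordings, sample_valid)
  ids <- vapply(group$recordings, function(r) r$subject_id, character(1))
  rows <- list()
  for (el in electrodes) {
    ei <- match(el, labs)
    pl <- vector("list", N * (N - 1) / 2)
    pi_ <- 0L
    for (j in seq_len(N - 1)) for (k in (j + 1):N) {
      pi_ <- pi_ + 1L
      res <- plv_pairwise(phases[[j]][ei, ], phases[[k]][ei, ], fs,
                          length = 5, hop = hop,
                          valid = valid[[j]] & valid[[k]])
      w_in <- rep(FALSE, res$grid$n_windows)
      sec_of <- rep(NA_character_, res$grid$n_windows)
      for (s in seq_len(nrow(sections))) {
        inw <- res$grid$starts >= sections$start[s] &
          (res$grid$starts + res$grid$length) <= sections$end[s]
        w_in <- w_in | inw
        sec_of[inw] <- sections$label[s]
      }
      if (!any(w_in)) next
      rows[[length(rows) + 1L]] <- data.frame(
        section = sec_of[w_in], subj_j = ids[j], subj_k = ids[k],
        electrode = el, region = region[[el]],
        window_start_s = res$grid$starts[w_in], plv = res$plv[w_in],
        T = res$T[w_in])
    }
  }
  if (!length(rows)) {
    warning("no analysis window fits inside any section")
    return(data.frame(section = character(), subj_j = character(),
                      subj_k = character(), electrode = character(),
                      region = character(), window_start_s = numeric(),
                      plv = numeric(), T = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments (mean removed
#' per segment), one-sided and scaled so that the integral of the PSD over
#' frequency equals the signal variance.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default 250, i.e. 1 s at
#'   250 Hz).
#' @param overlap fractional segment overlap (default 0.2).
#' @return list with `freq` (Hz), `psd` (power/Hz), `n_segments`.
#' @export
welch_psd <- function(x, fs, nperseg = 250L, overlap = 0.2) {
  n <- length(x)
  if (n < nperseg) stop("series shorter than one segment")
  hopn <- round(nperseg * (1 - overlap))
  starts <- seq(1L, n - nperseg + 1L, by = hopn)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))   # Hann
  U <- sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    half <- P[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    if (nperseg %% 2 == 1L) half[nf] <- 2 * half[nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts),
       n_segments = length(starts))
}

#' Mean band power of a recording section (Welch)
#'
#' Welch PSD per channel over the section (1 s Hann segments with 20%
#' overlap at 250 Hz), averaged across channels and then across the
#' frequency bins inside the band.
#'
#' @param rec a [recording()] (broadband; typically before band-passing).
#' @param band a [band_spec()].
#' @param section optional `c(start, end)` seconds; default the whole
#'   recording.
#' @param nperseg,overlap Welch parameters (defaults 1 s / 20%).
#' @return one-row data frame: subject, band, section, power (uV^2/Hz),
#'   n_segments.
#' @export
welch_band_power <- function(rec, band, section = NULL, nperseg = NULL,
                             overlap = 0.2) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  fs <- rec$sample_rate
  if (is.null(nperseg)) nperseg <- round(fs)
  sel <- if (is.null(section)) seq_len(ncol(rec$samples)) else {
    if (diff(section) < 1) stop("section must be at least 1 s")
    (round(section[1] * fs) + 1L):round(section[2] * fs)
  }
  if (length(sel) < nperseg) stop("section must be at least 1 s")
  per_ch <- apply(rec$samples[, sel, drop = FALSE], 1L, welch_psd, fs = fs,
                  nperseg = nperseg, overlap = overlap)
  freq <- per_ch[[1]]$freq
  mean_psd <- Reduce(`+`, lapply(per_ch, `[[`, "psd")) / length(per_ch)
  in_band <- freq >= band$low & freq <= band$high
  data.frame(subject = rec$subject_id, band = band$name,
             section = if (is.null(section)) "all" else
               sprintf("%g-%g", section[1], section[2]),
             power = mean(mean_psd[in_band]),
             n_segments = per_ch[[1]]$n_segments)
}

#' Remove outlying power rows
#'
#' Drops rows whose power lies beyond `sd` standard deviations of the mean
#' power (both computed over the input rows); the number removed is attached
#' as attribute `"n_dropped"`.
#'
#' @param rows data frame with a `power` column (>= 3 rows).
#' @param sd SD multiple (default 4).
#' @return filtered data frame.
#' @export
power_outlier_filter <- function(rows, sd = 4) {
  if (nrow(rows) < 3L) stop("need at least 3 rows")
  mu <- mean(rows$power)
  s <- stats::sd(rows$power)
  keep <- if (s == 0) rep(TRUE, nrow(rows)) else abs(rows$power - mu) <= sd * s
  out <- rows[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
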