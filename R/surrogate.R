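#' Circular-shift surrogate of a group recording
#'
#' Rotates each subject's full multichannel record (and mask) in time by an
#' independent uniform offset, destroying inter-subject alignment while
#' preserving each subject's within-record structure (variances, spectra,
#' autocorrelation up to wrap-around). Offsets are drawn uniformly from
#' `[30 s, duration - 30 s]` so that no surrogate is near-identical to the
#' original.
#'
#' @param group aligned [group_recording()] of at least 120 s.
#' @param seed integer seed for the offset draws.
#' @param offsets optional numeric vector of per-subject offsets in seconds,
#'   overriding the random draw (used e.g. to force a zero shift).
#' @return shifted `group_recording` with attribute `"offsets"` (seconds).
#' @export
circular_shift <- function(group, seed = 1L, offsets = NULL) {
  stopifnot(inherits(group, "group_recording"))
  dur <- rec_duration(group$recordings[[1]])
  N <- n_subjects(group)
  fs <- group$sample_rate
  if (is.null(offsets)) {
    if (dur < 120) stop("duration < 120 s: circular-shift offsets degenerate")
    offsets <- with_substream(seed, 0L, stats::runif(N, 30, dur - 30))
  }
  n <- ncol(group$recordings[[1]]$samples)
  for (k in seq_len(N)) {
    s <- round(offsets[k] * fs) %% n
    if (s > 0) {
      idx <- c((n - s + 1L):n, 1L:(n - s))
      group$recordings[[k]]$samples <- group$recordings[[k]]$samples[, idx, drop = FALSE]
      if (has_mask(group$recordings[[k]]))
        group$recordings[[k]]$mask <- group$recordings[[k]]$mask[, idx, drop = FALSE]
    }
  }
  attr(group, "offsets") <- offsets
  group
}

#' Surrogate null distribution of the time-resolved ISC
#'
#' Repeats (circular shift -> component fit -> time-resolved ISC of the first
#' component) `iterations` times, giving the per-window null distribution
#' against which the true ISC time course is thresholded (default: 95th
#' percentile per window).
#'
#' @param group aligned [group_recording()].
#' @param grid a [window_grid()].
#' @param iterations number of surrogates (study default 1000; < 100 warns,
#'   < 10 errors).
#' @param seed integer seed; iteration i uses sub-stream i.
#' @param level percentile level (default 95).
#' @param lambda shrinkage passed to [fit_cca()].
#' @param exclude_masked passed to [pooled_covariances()] for each surrogate
#'   refit; default `FALSE` (zeroed samples enter as zeros), since the
#'   sub-percent difference is invisible against surrogate variability and
#'   the pairwise-excluded pass is O(N^2) more expensive. Window statistics
#'   keep their pairwise mask handling regardless.
#' @return object of class `null_distribution` with `draws`
#'   (iterations x windows matrix of null ISC1), `level`, `band`, `grid`.
#' @export
null_isc_distribution <- function(group, grid, iterations = 1000L, seed = 1L,
                                  level = 95, lambda = 0.1,
                                  exclude_masked = FALSE) {
  if (iterations < 10L) stop("need at least 10 surrogate iterations")
  if (iterations < 100L) warning("fewer than 100 surrogate iterations")
  draws <- matrix(NA_real_, iterations, grid$n_windows)
  for (i in seq_len(iterations)) {
    sh <- circular_shift(group, seed = derive_seed(seed, i))
    model <- fit_cca_group(sh, n_components = 1L, lambda = lambda,
                           exclude_masked = exclude_masked)
    draws[i, ] <- isc_timecourse(sh, model, grid, components = 1L)$values
  }
  band_name <- if (!is.null(group$recordings[[1]]$band))
    group$recordings[[1]]$band$name else NA_character_
  structure(list(draws = draws, level = level, band = band_name, grid = grid),
            class = "null_distribution")
}

#' Per-window percentile threshold of a null distribution
#' @param null a [null_isc_distribution()] result.
#' @return numeric vector, one threshold per window.
#' @export
null_threshold <- function(null) {
  # quantile type 6: with K draws the exceedance probability of the
  # interpolated p-th order statistic is exactly 1 - p under exchangeability
  # (matters at a few hundred surrogates; immaterial at 1000)
  apply(null$draws, 2L, stats::quantile, probs = null$level / 100,
        na.rm = TRUE, names = FALSE, type = 6)
}

# Connected components on a bands x windows logical grid with 4-connectivity
# (adjacent windows within a band, same window in neighbouring bands).
# Returns an integer label matrix (0 = below threshold).
label_clusters <- function(supra) {
  B <- nrow(supra); W <- ncol(supra)
  lab <- matrix(0L, B, W)
  cur <- 0L
  for (b in seq_len(B)) for (w in seq_len(W)) {
    if (!supra[b, w] || lab[b, w] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(b, w), 1L)
    lab[b, w] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      nb <- rbind(c(p[1] - 1L, p[2]), c(p[1] + 1L, p[2]),
                  c(p[1], p[2] - 1L), c(p[1], p[2] + 1L))
      nb <- nb[nb[, 1] >= 1L & nb[, 1] <= B & nb[, 2] >= 1L & nb[, 2] <= W, ,
               drop = FALSE]
      for (j in seq_len(nrow(nb))) {
        bb <- nb[j, 1]; ww <- nb[j, 2]
        if (supra[bb, ww] && lab[bb, ww] == 0L) {
          lab[bb, ww] <- cur
          queue <- rbind(queue, c(bb, ww))
        }
      }
    }
  }
  lab
}

# Largest connected cluster size on a bands x windows logical grid.
max_cluster_size <- function(supra) {
  if (nrow(supra) == 1L) {                 # single band: runs of TRUE
    r <- rle(as.vector(supra))
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  } else {
    lab <- label_clusters(supra)
    if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
  }
}

#' Cluster-based correction of supra-threshold ISC time points
#'
#' Windows where the true first-component ISC exceeds the per-window
#' percentile threshold are grouped into connected clusters: contiguous
#' windows within a band, plus the same window in neighbouring bands (bands
#' ordered delta, theta, alpha, beta). The null distribution of cluster sizes
#' takes the largest cluster in each surrogate iteration (surrogates
#' thresholded against the same per-window percentiles); a true cluster is
#' significant when its size exceeds the 95th percentile of those maxima.
#'
#' @param true_series an `isc_series` or list of them (one per band, in band
#'   order).
#' @param nulls matching [null_isc_distribution()] or list of them.
#' @return object of class `cluster_set`: data frame `clusters` (band,
#'   start_window, end_window, start_s, end_s, size, significant),
#'   `null_max_sizes`, `size_threshold`.
#' @export
significant_clusters <- function(true_series, nulls) {
  if (inherits(true_series, "isc_series")) true_series <- list(true_series)
  if (inherits(nulls, "null_distribution")) nulls <- list(nulls)
  if (length(true_series) != length(nulls))
    stop("need one null distribution per band series")
  B <- length(true_series)
  W <- length(true_series[[1]]$values)
  for (b in seq_len(B)) {
    if (!identical(length(true_series[[b]]$values), W) ||
        ncol(nulls[[b]]$draws) != W)
      stop("grid mismatch between true series and null distribution")
  }
  thr <- lapply(nulls, null_threshold)
  supra <- do.call(rbind, lapply(seq_len(B), function(b) {
    v <- true_series[[b]]$values > thr[[b]]
    v & !is.na(v)
  }))
  iters <- nrow(nulls[[1]]$draws)
  null_max <- vapply(seq_len(iters), function(i) {
    s <- do.call(rbind, lapply(seq_len(B), function(b) {
      v <- nulls[[b]]$draws[i, ] > thr[[b]]
      v & !is.na(v)
    }))
    max_cluster_size(s)
  }, numeric(1))
  size_thr <- stats::quantile(null_max, 0.95, names = FALSE)
  lab <- label_clusters(supra)
  rows <- list()
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    for (cl in seq_len(max(lab))) {
      cells <- which(lab == cl, arr.ind = TRUE)
      for (b in unique(cells[, 1])) {
        wset <- sort(cells[cells[, 1] == b, 2])
        grid <- true_series[[b]]$grid
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, band = true_series[[b]]$band,
          start_window = min(wset), end_window = max(wset),
          start_s = grid$starts[min(wset)],
          end_s = grid$starts[max(wset)] + grid$length,
          size = sizes[cl], significant = sizes[cl] > size_thr)
      }
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), band = character(),
               start_window = integer(), end_window = integer(),
               start_s = numeric(), end_s = numeric(), size = integer(),
               significant = logical())
  structure(list(clusters = clusters, null_max_sizes = null_max,
                 size_threshold = size_thr, supra = supra),
            class = "cluster_set")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotone adjusted values, plus the rejection
#' set at level `q`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L)
    return(list(p_adjusted = numeric(0), rejected = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj < q)
}

#' Resting-state baseline contrast of the synchrony time course
#'
#' A pre-performance resting-state (RS) recording is tiled end-to-end to the
#' performance duration and pushed through the same component + windowed ISC
#' pipeline. For each consecutive `segment_length` segment of the
#' performance, the performance and RS window values are compared with a
#' paired Wilcoxon signed-rank test (pairing by window index within the
#' segment), BH-FDR corrected across segments.
#'
#' @param perf_isc `isc_series` of the performance (first component).
#' @param rs_group `group_recording` of resting-state data (same subjects,
#'   rate, channels; may be shorter than the performance).
#' @param segment_length segment length in seconds (default 150, i.e.
#'   2.5 min).
#' @param lambda shrinkage passed to [fit_cca()].
#' @return data frame: segment, start_s, end_s, n_windows, statistic, p,
#'   p_fdr, direction ("performance" or "rest" = larger side).
#' @export
rs_baseline_test <- function(perf_isc, rs_group, segment_length = 150,
                             lambda = 0.1) {
  stopifnot(inherits(perf_isc, "isc_series"),
            inherits(rs_group, "group_recording"))
  grid <- perf_isc$grid
  fs <- rs_group$sample_rate
  n_rs <- ncol(rs_group$recordings[[1]]$samples)
  if (n_rs / fs < segment_length)
    stop("resting-state recording shorter than one segment")
  n_perf <- round(grid$duration * fs)
  reps <- ceiling(n_perf / n_rs)
  tiled <- rs_group
  for (k in seq_len(n_subjects(rs_group))) {
    idx <- rep(seq_len(n_rs), reps)[seq_len(n_perf)]
    tiled$recordings[[k]]$samples <- rs_group$recordings[[k]]$samples[, idx, drop = FALSE]
    tiled$recordings[[k]]$mask <- rs_group$recordings[[k]]$mask[, idx, drop = FALSE]
  }
  rs_model <- fit_cca_group(tiled, n_components = 1L, lambda = lambda)
  rs_isc <- isc_timecourse(tiled, rs_model, grid, components = 1L)
  seg_starts <- seq(0, grid$duration - segment_length, by = segment_length)
  rows <- list()
  for (si in seq_along(seg_starts)) {
    s0 <- seg_starts[si]; s1 <- s0 + segment_length
    w <- which(grid$starts >= s0 & grid$starts < s1)
    a <- perf_isc$values[w]; b <- rs_isc$values[w]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 6L) {
      warning(sprintf("segment %d has < 6 usable windows; skipped", si))
      next
    }
    d <- a[ok] - b[ok]
    if (all(d == 0)) {
      stat <- NA_real_; p <- 1
    } else {
      wt <- stats::wilcox.test(a[ok], b[ok], paired = TRUE,
                               exact = sum(d != 0) < 25, correct = TRUE)
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      segment = si, start_s = s0, end_s = s1, n_windows = sum(ok),
      statistic = stat, p = p,
      direction = if (stats::median(d) >= 0) "performance" else "rest")
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- fdr_bh(res$p)$p_adjusted
  res[, c("segment", "start_s", "end_s", "n_windows", "statistic", "p",
          "p_fdr", "direction")]
}
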