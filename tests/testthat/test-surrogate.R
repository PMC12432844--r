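test_that("circular shift preserves within-subject structure exactly", {
  g <- make_shared_group(n_subj = 3, dur = 10, seed = 41)
  sh <- circular_shift(g, offsets = c(2, 4, 6))
  for (k in 1:3) {
    a <- g$recordings[[k]]$samples; b <- sh$recordings[[k]]$samples
    expect_equal(apply(a, 1, var), apply(b, 1, var))       # variance exact
    expect_equal(sort(a[1, ]), sort(b[1, ]))               # a pure rotation
  }
  # forced zero shift is the identity
  sh0 <- circular_shift(g, offsets = c(0, 0, 0))
  expect_equal(sh0$recordings[[1]]$samples, g$recordings[[1]]$samples)
  expect_error(circular_shift(g), "120 s")                 # too short to draw
})

test_that("rotation preserves the autocorrelation away from the wrap seam", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.9), 2500))
  rec <- recording(matrix(x, 1), 250)
  g <- group_recording(list(rec, recording(matrix(rnorm(2500), 1), 250)),
                       aligned = TRUE)
  sh <- circular_shift(g, offsets = c(4, 0))
  acf_a <- acf(g$recordings[[1]]$samples[1, ], lag.max = 20, plot = FALSE)$acf
  acf_b <- acf(sh$recordings[[1]]$samples[1, ], lag.max = 20, plot = FALSE)$acf
  expect_equal(as.numeric(acf_b), as.numeric(acf_a), tolerance = 0.05)
})

test_that("a forced zero-shift null draw reproduces the true ISC series", {
  g <- make_shared_group(n_subj = 3, dur = 130, seed = 43)
  grid <- window_grid(130)
  m <- fit_cca_group(g, n_components = 1L)
  true_series <- isc_timecourse(g, m, grid)
  sh <- circular_shift(g, offsets = rep(0, 3))
  m2 <- fit_cca_group(sh, n_components = 1L)
  expect_equal(isc_timecourse(sh, m2, grid)$values, true_series$values)
})

test_that("null distribution dimensions, guards, and thresholds are sane", {
  g <- make_shared_group(n_subj = 3, dur = 130, seed = 44)
  grid <- window_grid(130)
  expect_error(null_isc_distribution(g, grid, iterations = 5), "at least 10")
  expect_warning(nd <- null_isc_distribution(g, grid, iterations = 20,
                                             seed = 2), "fewer than 100")
  expect_identical(dim(nd$draws), c(20L, grid$n_windows))
  thr <- null_threshold(nd)
  expect_identical(length(thr), grid$n_windows)
  expect_true(all(thr >= apply(nd$draws, 2, min)))
  expect_true(all(thr <= apply(nd$draws, 2, max)))
})

test_that("cluster labelling groups time-adjacent and band-adjacent points", {
  grid <- window_grid(16, length = 5, hop = 1)   # 12 windows
  mk_series <- function(vals, band) structure(
    list(component = 1L, band = band, values = vals, grid = grid),
    class = "isc_series")
  mk_null <- function(level_vals) structure(
    list(draws = matrix(rep(level_vals, each = 40), 40), level = 95,
         band = "x", grid = grid), class = "null_distribution")
  # single band: exceedances at windows 3,4,5 and 9 -> clusters of 3 and 1
  v <- rep(0, 12); v[c(3, 4, 5, 9)] <- 1
  cs <- significant_clusters(mk_series(v, "delta"), mk_null(rep(0.5, 12)))
  expect_identical(sort(unique(cs$clusters$size)), c(1L, 3L))
  expect_identical(nrow(cs$clusters), 2L)
  # exceedance at window 7 in two neighbouring bands -> one cluster, size 2
  v7 <- rep(0, 12); v7[7] <- 1
  cs2 <- significant_clusters(list(mk_series(v7, "delta"),
                                   mk_series(v7, "theta")),
                              list(mk_null(rep(0.5, 12)),
                                   mk_null(rep(0.5, 12))))
  expect_identical(unique(cs2$clusters$cluster), 1L)
  expect_identical(unique(cs2$clusters$size), 2L)
  expect_identical(nrow(cs2$clusters), 2L)       # one row per band
})

test_that("grid mismatch between series and null is refused", {
  grid <- window_grid(16)
  s <- structure(list(component = 1L, band = "delta", values = rep(0, 12),
                      grid = grid), class = "isc_series")
  nd <- structure(list(draws = matrix(0, 10, 5), level = 95, band = "delta",
                       grid = window_grid(9)), class = "null_distribution")
  expect_error(significant_clusters(s, nd), "grid mismatch")
})

test_that("BH adjustment matches the closed form and edge cases", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5))
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_bh(0.2)$p_adjusted, 0.2)                # single p unchanged
  expect_false(any(fdr_bh(rep(1, 6))$rejected))
  expect_true(all(fdr_bh(rep(0.001, 10))$rejected))
  expect_identical(length(fdr_bh(numeric(0))$p_adjusted), 0L)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("resting-state identical to performance yields no significant segment", {
  g <- make_shared_group(n_subj = 3, dur = 300, seed = 45)
  grid <- window_grid(300)
  m <- fit_cca_group(g, n_components = 1L)
  perf <- isc_timecourse(g, m, grid)
  res <- rs_baseline_test(perf, g, segment_length = 150)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$p == 1))
  expect_false(any(res$p_fdr < 0.05))
})

test_that("synchronized performance beats a desynchronized resting baseline", {
  # performance: strong shared source; RS: independent noise
  perf_g <- make_shared_group(n_subj = 4, dur = 300, snr = 2, seed = 46)
  rs_g <- make_shared_group(n_subj = 4, dur = 160, snr = 0, seed = 47)
  grid <- window_grid(300)
  m <- fit_cca_group(perf_g, n_components = 1L)
  perf <- isc_timecourse(perf_g, m, grid)
  res <- rs_baseline_test(perf, rs_g, segment_length = 150)
  expect_true(all(res$p_fdr < 0.05))
  expect_true(all(res$direction == "performance"))
})
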