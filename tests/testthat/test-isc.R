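test_that("window grid arithmetic matches the 5 s / 1 s hop convention", {
  g <- window_grid(60)
  expect_identical(g$n_windows, 56L)            # floor((60-5)/1)+1
  expect_equal(g$starts[1], 0)
  expect_equal(g$starts[56], 55)
  expect_error(window_grid(3), "shorter")
})

test_that("pooled covariances obey the identical- and two-subject identities", {
  g3 <- make_identical_group(n_subj = 3)
  cv <- pooled_covariances(g3)
  expect_equal(cv$Rb, (3 - 1) * cv$Rw)          # R_kl = R_kk for all pairs
  g2 <- make_identical_group(n_subj = 2, seed = 8)
  x <- g2$recordings[[1]]$samples
  x2 <- x + matrix(rnorm(length(x)), nrow(x))
  g2$recordings[[2]]$samples <- x2
  cv2 <- pooled_covariances(g2)
  xc <- x - rowMeans(x); x2c <- x2 - rowMeans(x2)
  R12 <- tcrossprod(xc, x2c) / (ncol(x) - 1)
  expect_equal(cv2$Rb, (R12 + t(R12)), ignore_attr = TRUE)   # Rb = R12 + R21
})

test_that("between-subject covariance vanishes for independent subjects", {
  g <- make_shared_group(n_subj = 4, snr = 0, dur = 120, seed = 5)
  cv <- pooled_covariances(g)
  expect_lt(norm(cv$Rb, "F") / norm(cv$Rw, "F"), 0.05)
})

test_that("identical subjects give first-component ISC exactly 1", {
  g <- make_identical_group(n_subj = 5)
  cv <- pooled_covariances(g)
  m <- fit_cca(cv$Rw, cv$Rb, 5, lambda = 0)
  expect_equal(m$isc[1], 1, tolerance = 1e-10)
  tc <- isc_timecourse(g, m, window_grid(20))
  expect_equal(tc$values, rep(1, 16), tolerance = 1e-10)
})

test_that("independent white-noise subjects give near-zero ISC", {
  set.seed(9)
  recs <- lapply(1:4, function(k) recording(matrix(rnorm(4 * 250 * 600), 4), 250))
  g <- group_recording(recs, aligned = TRUE)
  m <- fit_cca_group(g, lambda = 0)
  expect_lte(m$isc[1], 0.05)
})

test_that("eigen solution matches brute-force ratio maximization on 2 channels", {
  for (seed in 1:3) {
    set.seed(seed)
    A <- matrix(rnorm(4), 2); Rw <- crossprod(A) + diag(2)
    B <- matrix(rnorm(4), 2); Rb <- (B + t(B)) / 2
    N <- 4
    ang <- (0:179) * pi / 180
    brute <- max(vapply(ang, function(a) {
      v <- c(cos(a), sin(a))
      (v %*% Rb %*% v) / ((N - 1) * v %*% Rw %*% v)
    }, numeric(1)))
    m <- fit_cca(Rw, Rb, N, lambda = 0)
    expect_lt(abs(m$isc[1] - brute), 1e-4)
    expect_gte(m$isc[1] + 1e-10, brute)          # eigen solution is the max
  }
})

test_that("no random unit vector beats the fitted first component", {
  g <- make_shared_group(n_subj = 4, dur = 30, seed = 13)
  cv <- pooled_covariances(g)
  m <- fit_cca(cv$Rw, cv$Rb, 4, lambda = 0)
  set.seed(14)
  ratios <- replicate(1000, {
    v <- rnorm(4); v <- v / sqrt(sum(v^2))
    (v %*% cv$Rb %*% v) / ((4 - 1) * v %*% cv$Rw %*% v)
  })
  expect_gte(m$isc[1], max(ratios) - 1e-10)
})

test_that("ISC is invariant to a common channel-wise rescaling", {
  g <- make_shared_group(n_subj = 3, dur = 30, seed = 15)
  scale <- c(2, 0.5, 7, 1.3)
  g2 <- group_map(g, function(r) { r$samples <- r$samples * scale; r })
  # exact CCA (no diagonal loading); the isotropic shrinkage term is the
  # one deliberately scale-dependent part of the regularized fit
  m1 <- fit_cca_group(g, lambda = 0)
  m2 <- fit_cca_group(g2, lambda = 0)
  expect_equal(m2$isc, m1$isc, tolerance = 1e-6)
  t1 <- isc_timecourse(g, m1, window_grid(30))
  t2 <- isc_timecourse(g2, m2, window_grid(30))
  expect_equal(t2$values, t1$values, tolerance = 1e-6)
})

test_that("windowed covariances aggregate back to the full-span covariances", {
  g <- make_shared_group(n_subj = 3, dur = 30, seed = 16)
  grid <- window_grid(30, length = 5, hop = 5)     # disjoint tiling
  full <- pooled_covariances(g)
  parts <- lapply(grid$starts, function(s)
    pooled_covariances(g, span = c(s, s + 5)))
  n_w <- 5 * 250
  # sample-weighted second moments reassemble (means differ per span, so
  # compare at loose tolerance relative to scale)
  Rw_sum <- Reduce(`+`, lapply(parts, `[[`, "Rw")) / length(parts)
  expect_equal(Rw_sum, full$Rw, tolerance = 0.02)
})

test_that("windows with mostly masked samples come back missing", {
  g <- make_identical_group(n_subj = 3, dur = 20)
  for (k in 1:3) {
    g$recordings[[k]]$mask[, 1:(6 * 250)] <- TRUE
    g$recordings[[k]]$samples[, 1:(6 * 250)] <- 0
    g$recordings[[k]]$has_mask <- TRUE
  }
  m <- fit_cca_group(g, lambda = 0)
  tc <- isc_timecourse(g, m, window_grid(20))
  expect_true(all(is.na(tc$values[1:4])))        # fully masked windows
  expect_true(all(is.finite(tc$values[8:16])))   # clean windows
  expect_equal(tc$values[10], 1, tolerance = 1e-10)
})

test_that("a gain step raises second-half windowed ISC in every replicate", {
  step_gain <- function(t) as.numeric(t >= 60)
  wins <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_subjects = 4, n_channels = 4, duration = 120,
                      sample_rate = 100, snr = 2, artifact_rate = 0,
                      coupling_beta = 0, device_offsets = rep(0, 4),
                      gain_profile = step_gain, seed = seed)
    sim <- simulate_audience(cfg)
    gb <- group_map(sim$group, bandpass_filter, band = canonical_bands()$delta)
    m <- fit_cca_group(gb)
    tc <- isc_timecourse(gb, m, window_grid(120))
    half <- tc$grid$starts < 55                  # keep windows fully in a half
    median(tc$values[!half & tc$grid$starts >= 60], na.rm = TRUE) >
      median(tc$values[half], na.rm = TRUE)
  }, logical(1))
  expect_identical(sum(wins), 10L)
})

test_that("explained covariance percentages behave as a composition", {
  m <- structure(list(isc_all = c(0.4, 0, 0, 0)), class = "cca_model")
  expect_equal(explained_covariance(m), c(100, 0, 0, 0))
  m$isc_all <- c(0.2, 0.2, 0.2, 0.2)
  expect_equal(explained_covariance(m), rep(25, 4))
  m$isc_all <- c(0.5, 0.3, -0.2, 0.1)
  expect_equal(sum(explained_covariance(m)), 100)
  m$isc_all <- c(-0.1, -0.5)
  expect_error(explained_covariance(m), "undefined")
})
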