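test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(duration = -5), "positive")
  expect_error(sim_config(band = band_spec("x", 10, 200)), "Nyquist")
  expect_error(sim_config(snr = -1), "snr")
  expect_error(sim_config(coupling_lag = 700, duration = 600), "coupling_lag")
})

test_that("fixed seed gives bit-identical output; seeds differ", {
  cfg <- sim_config(n_subjects = 3, n_channels = 4, duration = 30, seed = 5)
  a <- simulate_audience(cfg)
  b <- simulate_audience(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_subjects = 3, n_channels = 4, duration = 30, seed = 6)
  expect_false(identical(simulate_audience(cfg2)$group, a$group))
})

test_that("noise-only variance matches its unit configuration within 5%", {
  cfg <- sim_config(n_subjects = 2, n_channels = 8, duration = 120,
                    snr = 0, artifact_rate = 0, device_offsets = c(0, 0),
                    seed = 31)
  sim <- simulate_audience(cfg)
  v <- apply(sim$group$recordings[[1]]$samples, 1L, var)
  expect_true(all(abs(v - 1) < 0.05))
  # configured inter-channel noise correlation ~0.3
  cm <- cor(t(sim$group$recordings[[1]]$samples))
  expect_equal(mean(cm[upper.tri(cm)]), 0.3, tolerance = 0.05)
})

test_that("mixing vectors are unit norm and gain stays in [0, 1]", {
  cfg <- sim_config(n_subjects = 3, n_channels = 6, duration = 60, seed = 32)
  sim <- simulate_audience(cfg)
  expect_equal(colSums(sim$truth$mixing^2), rep(1, 3), tolerance = 1e-12)
  expect_true(all(sim$truth$gain >= 0 & sim$truth$gain <= 1))
  expect_identical(length(sim$truth$gain), 60L)
})

test_that("identical subjects with zero noise give windowed ISC exactly 1", {
  # noise off, common mixing, flat gain: all subjects identical
  cfg <- sim_config(n_subjects = 3, n_channels = 4, duration = 30, snr = 1,
                    artifact_rate = 0, coupling_beta = 0,
                    device_offsets = rep(0, 3),
                    gain_profile = function(t) rep(1, length(t)), seed = 33)
  sim <- simulate_audience(cfg)
  common <- sim$truth$mixing[, 1]
  src <- sim$truth$source
  recs <- lapply(1:3, function(k)
    recording(outer(common, src), 250, subject_id = paste0("S", k)))
  g <- group_recording(recs, aligned = TRUE)
  m <- fit_cca_group(g, n_components = 1L, lambda = 0)
  tc <- isc_timecourse(g, m, window_grid(30))
  expect_equal(tc$values, rep(1, tc$grid$n_windows), tolerance = 1e-8)
})

test_that("median windowed ISC increases with simulated snr", {
  snrs <- c(0, 0.5, 1, 2)
  med <- vapply(snrs, function(s) {
    vals <- vapply(1:5, function(rep) {
      cfg <- sim_config(n_subjects = 4, n_channels = 4, duration = 60,
                        sample_rate = 100, snr = s, artifact_rate = 0,
                        coupling_beta = 0, device_offsets = rep(0, 4),
                        seed = 100 * rep + round(10 * s))
      sim <- simulate_audience(cfg)
      gb <- group_map(sim$group, bandpass_filter,
                      band = canonical_bands()$delta)
      m <- fit_cca_group(gb)
      median(isc_timecourse(gb, m, window_grid(60))$values, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("artifact bursts trip the outlier-zeroing stage", {
  cfg <- sim_config(n_subjects = 2, n_channels = 4, duration = 60, snr = 0,
                    artifact_rate = 6, artifact_scale = 10,
                    device_offsets = c(0, 0), seed = 34)
  sim <- simulate_audience(cfg)
  expect_gt(length(sim$truth$artifact_times[[1]]), 0)
  z <- zero_outliers(sim$group$recordings[[1]])
  expect_gt(attr(z, "fraction_zeroed"), 0)
  # zeroed regions should cover the planted artifact onsets
  t0 <- sim$truth$artifact_times[[1]][1]
  idx <- round(t0 * 250) + seq_len(round(0.2 * 250))
  expect_gt(mean(z$mask[, idx]), 0)
})

test_that("simulated features include a coupled and an independent series", {
  cfg <- sim_config(n_subjects = 2, n_channels = 2, duration = 120,
                    coupling_beta = 1, coupling_lag = 3, seed = 35)
  sim <- simulate_audience(cfg)
  feats <- simulate_features(cfg, sim$truth, n_independent = 2)
  expect_named(feats, c("coupled", "independent1", "independent2"))
  expect_identical(length(feats$coupled$values), 120L)
  # the coupled feature leads the gain by the planted lag
  g <- sim$truth$gain; f <- feats$coupled$values
  cc <- sapply(0:8, function(l)
    cor(g[(l + 1):length(g)], f[1:(length(f) - l)]))
  expect_identical(which.max(cc) - 1L, 3L)
  # independent series does not correlate with the gain
  expect_lt(max(abs(sapply(0:8, function(l)
    cor(g[(l + 1):length(g)], feats$independent1$values[1:(length(g) - l)])))),
    0.5)
})

test_that("photoresistor traces encode per-device blackout offsets", {
  offs <- c(0, 0.2, -0.1)
  cfg <- sim_config(n_subjects = 3, n_channels = 2, duration = 60,
                    device_offsets = offs, blackout_time = 12, seed = 36)
  # zero noise, zero offsets -> recovered shifts exactly zero
  cfg0 <- sim_config(n_subjects = 3, n_channels = 2, duration = 60,
                     device_offsets = c(0, 0, 0), blackout_time = 12,
                     seed = 36)
  tr0 <- simulate_photoresistor(cfg0, noise_sd = 0)
  on0 <- vapply(tr0, function(x) detect_light_onset(x, 250)$time, numeric(1))
  expect_equal(on0 - on0[1], c(0, 0, 0))
  tr <- simulate_photoresistor(cfg)   # default measurement noise
  on <- vapply(tr, function(x) detect_light_onset(x, 250)$time, numeric(1))
  expect_lte(max(abs((on - on[1]) - (offs[1] - offs))), 2.5 / 250)
})

test_that("respiration traces share a slow common rhythm", {
  cfg <- sim_config(n_subjects = 3, n_channels = 2, duration = 60, seed = 37)
  tr <- simulate_respiration(cfg, rate = 500)
  cleaned <- lapply(tr, clean_respiration, rate = 500)
  cm <- cor(do.call(cbind, cleaned))
  expect_gt(mean(cm[upper.tri(cm)]), 0.3)
})
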