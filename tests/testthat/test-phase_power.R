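band_rec <- function(x, fs = 250, band = canonical_bands()$delta, n_ch = 1) {
  r <- recording(matrix(rep(x, n_ch), nrow = n_ch, byrow = TRUE), fs)
  r$band <- band
  r
}

test_that("instantaneous phase advances at the oscillation frequency", {
  fs <- 250; f0 <- 2
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(band_rec(sin(2 * pi * f0 * t)))
  un <- unwrap_phase(ph[1, ])
  mid <- 1000:4000
  rates <- diff(un[mid]) * fs / (2 * pi)
  expect_lt(max(abs(rates - f0) / f0), 0.01)
})

test_that("cosine phase leads sine phase by pi/2 and phase ignores amplitude", {
  fs <- 250; f0 <- 2
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ps <- instantaneous_phase(band_rec(sin(2 * pi * f0 * t)))[1, ]
  pc <- instantaneous_phase(band_rec(cos(2 * pi * f0 * t)))[1, ]
  d <- Arg(exp(1i * (pc - ps)))
  mid <- 500:2000
  expect_equal(mean(d[mid]), pi / 2, tolerance = 1e-3)
  p5 <- instantaneous_phase(band_rec(5 * sin(2 * pi * f0 * t)))[1, ]
  expect_equal(p5[mid], ps[mid], tolerance = 1e-9)
  expect_warning(instantaneous_phase(recording(matrix(rnorm(2500), 1), 250)),
                 "band")
})

test_that("PLV hits its analytic fixed points", {
  fs <- 250
  theta <- 2 * pi * 2 * seq(0, 10 - 1 / fs, by = 1 / fs)
  same <- plv_pairwise(theta, theta, fs)
  expect_equal(same$plv, rep(1, same$grid$n_windows))
  offs <- plv_pairwise(theta, theta + 1.1, fs)     # constant offset
  expect_equal(offs$plv, rep(1, offs$grid$n_windows))
  # phase difference sweeping a full cycle per window: complete roots of unity
  Tn <- 5 * fs
  dphi <- 2 * pi * (seq_len(10 * fs) - 1) / Tn
  roots <- plv_pairwise(theta + dphi, theta, fs, hop = 5)
  expect_equal(roots$plv, rep(0, roots$grid$n_windows), tolerance = 1e-10)
})

test_that("independent phases give the Rayleigh mean PLV", {
  set.seed(81)
  n <- 400 * 1250                                  # 400 disjoint 5 s windows
  a <- runif(n, -pi, pi); b <- runif(n, -pi, pi)
  res <- plv_pairwise(a, b, 250, hop = 5)
  expect_equal(mean(res$plv), sqrt(pi) / (2 * sqrt(1250)), tolerance = 0.05)
})

test_that("PLV is symmetric, bounded, and NA when windows are mostly masked", {
  set.seed(82)
  a <- runif(2500, -pi, pi); b <- runif(2500, -pi, pi)
  jk <- plv_pairwise(a, b, 250)
  kj <- plv_pairwise(b, a, 250)
  expect_equal(jk$plv, kj$plv)
  expect_true(all(jk$plv >= 0 & jk$plv <= 1))
  valid <- rep(TRUE, 2500); valid[1:1000] <- FALSE
  masked <- plv_pairwise(a, b, 250, valid = valid)
  expect_true(is.na(masked$plv[1]))
  expect_false(is.na(masked$plv[6]))
})

test_that("phase-coupling strength maps monotonically onto mean PLV", {
  set.seed(83)
  kappas <- c(0.2, 0.5, 1, 2, 4)
  mplv <- vapply(kappas, function(k) {
    # von Mises phase differences via wrapped normal approximation at 1/k
    mean(replicate(50, Mod(mean(exp(1i * rnorm(1250, sd = 1 / sqrt(k)))))))
  }, numeric(1))
  expect_gte(cor(kappas, mplv, method = "spearman"), 0.95)
  expect_true(all(diff(mplv) > 0))
})

test_that("section PLV covers all pairs and the named electrode sets", {
  fs <- 250
  labs <- c("C3", "C4", "Cz", "O1", "Oz", "O2", "Fz", "Pz")
  set.seed(84)
  recs <- lapply(1:5, function(k) {
    r <- recording(matrix(rnorm(8 * 20 * fs), 8), fs, channel_labels = labs,
                   subject_id = sprintf("S%02d", k))
    bandpass_filter(r, canonical_bands()$delta)
  })
  g <- group_recording(recs, aligned = TRUE)
  sections <- data.frame(label = "A", start = 2, end = 12)
  plv <- section_plv(g, sections)
  expect_identical(sort(unique(plv$electrode)),
                   sort(c("C3", "C4", "Cz", "O1", "Oz", "O2")))
  expect_identical(unique(plv$region[plv$electrode == "C3"]), "central")
  expect_identical(unique(plv$region[plv$electrode == "O1"]), "occipital")
  pairs <- unique(plv[, c("subj_j", "subj_k")])
  expect_equal(nrow(pairs), choose(5, 2))
  expect_error(section_plv(g, sections, electrodes = "XX"), "unknown electrode")
  expect_warning(section_plv(g, data.frame(label = "B", start = 2, end = 4)),
                 "no analysis window")
})

test_that("audience pair counts match the combinatorial expectation", {
  expect_identical(choose(20, 2), 190)
  expect_identical(choose(18, 2), 153)
  expect_identical(choose(21, 2), 210)
  # non-overlapping 5 s windows give 36 windows per 3-minute section
  g36 <- window_grid(180, length = 5, hop = 5)
  expect_identical(g36$n_windows, 36L)
})

test_that("Welch segmentation and scaling follow their definitions", {
  set.seed(85)
  w <- welch_psd(rnorm(1000), fs = 250, nperseg = 250, overlap = 0.2)
  expect_identical(w$n_segments, 4L)             # floor((1000-250)/200)+1
  x <- rnorm(250 * 120)
  ww <- welch_psd(x, 250)
  expect_equal(sum(ww$psd) * (250 / 250), var(x), tolerance = 0.05)
})

test_that("a 10 Hz tone concentrates power in alpha, not delta", {
  t <- seq(0, 60 - 1 / 250, by = 1 / 250)
  rec <- recording(matrix(sin(2 * pi * 10 * t), 1), 250, subject_id = "S1")
  alpha <- welch_band_power(rec, canonical_bands()$alpha)
  delta <- welch_band_power(rec, canonical_bands()$delta)
  expect_gt(alpha$power / delta$power, 100)
  expect_error(welch_band_power(rec, canonical_bands()$alpha,
                                section = c(0, 0.5)), "1 s")
})

test_that("power outlier filtering drops only extreme rows and is stable", {
  set.seed(86)
  # a single spike can only exceed 4 contaminated SDs in a large-enough
  # sample (max attainable z is (n-1)/sqrt(n)); use an audience-sized table
  rows <- data.frame(subject = sprintf("S%d", 1:30), band = "delta",
                     power = c(rnorm(29, 10, 0.5), 10))
  expect_identical(attr(power_outlier_filter(rows), "n_dropped"), 0L)
  rows$power[30] <- 10 + 10 * sd(rows$power[1:29])
  f1 <- power_outlier_filter(rows)
  expect_identical(attr(f1, "n_dropped"), 1L)
  expect_false("S30" %in% f1$subject)
  f2 <- power_outlier_filter(f1)
  expect_identical(attr(f2, "n_dropped"), 0L)
  expect_error(power_outlier_filter(rows[1:2, ]), "3 rows")
})
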