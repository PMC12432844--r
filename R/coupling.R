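# Dickey-Fuller tau distribution, constant-only regression (tau_mu):
# finite-sample quantiles by series length, used for response-surface
# interpolation of the p-value (the standard table approach).
.df_tau_mu <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  probs = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  q = rbind(
    c(-3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)))

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root screen used before Granger analysis. Fits
#' `diff(y)_t = a + rho * y_{t-1} + sum_i phi_i diff(y)_{t-i} + e_t`
#' (constant, no trend), choosing the augmentation order by AIC up to
#' `floor(12 * (n/100)^0.25)`, and interpolates the p-value of the t-statistic
#' on `rho` from the constant-only Dickey-Fuller quantile table (over both
#' sample size and level). `stationary` is `p < 0.05` (unit root rejected).
#'
#' @param series numeric series, length >= 50.
#' @param max_lag optional cap on the augmentation order.
#' @return list with `statistic`, `p`, `lag` (chosen order), `stationary`.
#' @export
adf_test <- function(series, max_lag = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 50L) stop("series must have length >= 50")
  if (stats::sd(series) == 0) stop("constant series: ADF undefined")
  if (is.null(max_lag)) max_lag <- floor(12 * (n / 100)^0.25)
  dy <- diff(series)
  ylag <- series[-n]
  fit_one <- function(p) {
    # common estimation sample across candidate orders is not required for
    # the final fit; AIC comparison below uses the largest common sample
    idx <- (max_lag + 1L):length(dy)
    X <- cbind(1, ylag[idx])
    if (p > 0) for (i in seq_len(p)) X <- cbind(X, dy[idx - i])
    y <- dy[idx]
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    k <- ncol(X)
    nn <- length(y)
    aic <- nn * log(rss / nn) + 2 * k
    list(fit = fit, aic = aic, rss = rss, nn = nn, k = k, p = p)
  }
  fits <- lapply(0:max_lag, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  # refit at the chosen order on its own maximal sample
  p <- best$p
  idx <- (p + 1L):length(dy)
  X <- cbind(1, ylag[idx])
  if (p > 0) for (i in seq_len(p)) X <- cbind(X, dy[idx - i])
  y <- dy[idx]
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(y) - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se
  # interpolate quantile rows to this sample size, then level over statistic
  tab <- .df_tau_mu
  qn <- vapply(seq_along(tab$probs), function(j)
    stats::approx(tab$n, tab$q[, j], xout = min(n, 500), rule = 2)$y,
    numeric(1))
  pval <- stats::approx(qn, tab$probs, xout = stat, rule = 2)$y
  list(statistic = unname(stat), p = unname(pval), lag = p,
       stationary = pval < 0.05)
}

#' First difference of a series
#'
#' Applied to predictors that fail the stationarity screen (e.g. stage
#' lighting).
#'
#' @param series numeric series, length >= 2.
#' @return differenced series, length `n - 1`.
#' @export
difference_series <- function(series) {
  if (length(series) < 2L) stop("need length >= 2")
  diff(series)
}

# Build the lagged design for a nested Granger regression.
lag_matrix <- function(x, p, n) {
  sapply(seq_len(p), function(i) x[(p - i + 1L):(n - i)])
}

#' Pairwise Granger-causality test at one lag order
#'
#' Tests whether past `predictor` improves prediction of `outcome` beyond
#' `outcome`'s own past: restricted model = outcome on its own lags
#' `1..lag`; unrestricted adds the predictor's lags `1..lag`; SSR-based F
#' with `(lag, n_eff - 2*lag - 1)` degrees of freedom. Rank-deficient
#' (collinear) lag designs fall back to a small ridge with a warning.
#'
#' @param outcome,predictor numeric series of equal length (both assumed
#'   stationary or pre-differenced).
#' @param lag lag order (positive integer; 1 s steps on the 1 Hz clock).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
granger_pairwise <- function(outcome, predictor, lag) {
  n <- length(outcome)
  if (length(predictor) != n) stop("series lengths differ")
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be a positive integer")
  if (n <= 3L * lag + 10L) stop("series too short for this lag order")
  y <- outcome[(lag + 1L):n]
  Yl <- lag_matrix(outcome, lag, n)
  Xl <- lag_matrix(predictor, lag, n)
  Xr <- cbind(1, Yl)
  Xu <- cbind(Xr, Xl)
  solve_ols <- function(X, y) {
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) {
      warning("collinear lag design; ridge fallback")
      G <- crossprod(X) + 1e-8 * mean(diag(crossprod(X))) * diag(ncol(X))
      b <- solve(G, crossprod(X, y))
      sum((y - X %*% b)^2)
    } else {
      sum(qr.resid(qr_, y)^2)
    }
  }
  ssr_r <- solve_ols(Xr, y)
  ssr_u <- solve_ols(Xu, y)
  df1 <- lag
  df2 <- length(y) - 2L * lag - 1L
  Fstat <- ((ssr_r - ssr_u) / df1) / (ssr_u / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Lag-resolved Granger scan from features to a synchrony time course
#'
#' Runs [granger_pairwise()] for every (predictor, lag) cell over lags
#' `1..max_lag`, each lag reported separately (mirroring per-lag heatmaps
#' rather than selecting one order), with BH-FDR across the whole grid (the
#' declared family: all predictor x lag cells per outcome). Predictors and
#' the outcome are screened with [adf_test()] first; a non-stationary series
#' is refused unless `auto_difference = TRUE`, in which case it is first-
#' differenced (and the outcome trimmed to match for that predictor).
#'
#' The identical scan can be run against a surrogate synchrony course to
#' check that apparent coupling vanishes under the null.
#'
#' @param outcome numeric series (e.g. windowed first-component delta ISC on
#'   the 1 s grid).
#' @param predictors named list of numeric series (or [feature_series()])
#'   on the same 1 Hz clock.
#' @param lags lag orders to scan (default `1:15` seconds).
#' @param q FDR level (default 0.05).
#' @param screen run the ADF screen (default TRUE).
#' @param auto_difference difference non-stationary predictors instead of
#'   refusing (default FALSE).
#' @return data frame of class `granger_scan`: predictor, lag, F, p, p_fdr,
#'   significant; attribute `"adf"` holds the screening results.
#' @export
granger_scan <- function(outcome, predictors, lags = 1:15, q = 0.05,
                         screen = TRUE, auto_difference = FALSE) {
  if (inherits(outcome, "isc_series")) outcome <- outcome$values
  outcome <- as.numeric(outcome)
  predictors <- lapply(predictors, function(p)
    if (inherits(p, "feature_series")) p$values else as.numeric(p))
  if (length(predictors) == 0L) {
    out <- data.frame(predictor = character(), lag = integer(), F = numeric(),
                      p = numeric(), p_fdr = numeric(), significant = logical())
    class(out) <- c("granger_scan", "data.frame")
    return(out)
  }
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("x", seq_along(predictors))
  adf <- list()
  if (screen) {
    adf$outcome <- adf_test(outcome)
    for (nm in names(predictors)) {
      a <- adf_test(predictors[[nm]])
      if (!a$stationary) {
        if (!auto_difference)
          stop(sprintf(paste0("predictor '%s' fails the stationarity screen ",
                              "(ADF p = %.3f); difference it or set ",
                              "auto_difference = TRUE"), nm, a$p))
        predictors[[nm]] <- difference_series(predictors[[nm]])
        a <- c(a, differenced = TRUE)
      }
      adf[[nm]] <- a
    }
  }
  rows <- list()
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    yy <- outcome
    if (length(x) < length(yy)) yy <- yy[(length(yy) - length(x) + 1L):length(yy)]
    if (length(x) > length(yy)) x <- x[(length(x) - length(yy) + 1L):length(x)]
    for (lg in lags) {
      g <- granger_pairwise(yy, x, lg)
      rows[[length(rows) + 1L]] <- data.frame(predictor = nm, lag = lg,
                                              F = g$F, p = g$p)
    }
  }
  out <- do.call(rbind, rows)
  bh <- fdr_bh(out$p, q = q)
  out$p_fdr <- bh$p_adjusted
  out$significant <- bh$rejected
  attr(out, "adf") <- adf
  class(out) <- c("granger_scan", "data.frame")
  out
}

#' Minimal significant lag per predictor of a Granger scan
#' @param scan a [granger_scan()] result.
#' @return named integer vector (NA where no lag is significant).
#' @export
minimal_significant_lag <- function(scan) {
  preds <- unique(scan$predictor)
  out <- vapply(preds, function(nm) {
    s <- scan[scan$predictor == nm & scan$significant, "lag"]
    if (length(s)) min(s) else NA_integer_
  }, integer(1))
  names(out) <- preds
  out
}
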