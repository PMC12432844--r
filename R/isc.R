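#' Time-resolved analysis window grid
#'
#' Half-open windows `[start, start + length)` tiling the recording span.
#' Defaults (5 s windows, 1 s hop, i.e. 80% overlap) give the grid used by
#' the time-resolved synchrony analyses; window timestamp = window start.
#'
#' @param duration recording duration in seconds.
#' @param length window length in seconds (default 5).
#' @param hop hop between window starts in seconds (default 1).
#' @return object of class `window_grid` with `$starts` (seconds) and
#'   `$n_windows`.
#' @export
window_grid <- function(duration, length = 5, hop = 1) {
  if (duration < length) stop("duration shorter than one window")
  starts <- seq(0, duration - length, by = hop)
  structure(list(length = length, hop = hop, starts = starts,
                 n_windows = base::length(starts), duration = duration),
            class = "window_grid")
}

# Window start indices (1-based) and window length in samples at rate fs.
grid_samples <- function(grid, fs) {
  list(start = round(grid$starts * fs) + 1L,
       len = round(grid$length * fs))
}

# Windowed sums of a series for every window: sum(x[start_w .. start_w+len-1]).
wsum <- function(x, starts, len) {
  cs <- c(0, cumsum(x))
  cs[starts + len] - cs[starts]
}

#' Pooled within- and between-subject channel covariances
#'
#' For subjects k, l the channel cross-covariance `R_kl` is computed over the
#' requested span (channel means removed per span; samples masked in either
#' subject are excluded pairwise). The pooled within-subject covariance is
#' `Rw = sum_k R_kk`; the pooled between-subject covariance is
#' `Rb = sum_{k != l} R_kl`, symmetrized as `(Rb + Rb')/2`.
#'
#' @param group an aligned [group_recording()] with identical channels.
#' @param span optional `c(start, end)` in seconds (half-open); default full
#'   recording.
#' @param exclude_masked drop masked samples pairwise (default `TRUE`). With
#'   `FALSE`, zeroed samples enter the cross-products as zeros; at the
#'   typical sub-percent masked fractions this changes the pooled
#'   covariances by well under 1% and avoids the O(N^2) pairwise pass --
#'   used by the surrogate loop, where hundreds of refits are needed.
#' @return list with `Rw`, `Rb` (channels x channels) and `n` (subjects).
#' @export
pooled_covariances <- function(group, span = NULL, exclude_masked = TRUE) {
  stopifnot(inherits(group, "group_recording"))
  N <- n_subjects(group)
  fs <- group$sample_rate
  n_tot <- ncol(group$recordings[[1]]$samples)
  sel <- if (is.null(span)) seq_len(n_tot) else {
    i0 <- round(span[1] * fs) + 1L
    i1 <- round(span[2] * fs)
    if (i0 < 1L || i1 > n_tot || i1 - i0 < 1L) stop("span outside recording")
    i0:i1
  }
  any_masked <- exclude_masked && any(vapply(group$recordings, function(r)
    has_mask(r) && any(r$mask[, sel]), logical(1)))
  X <- lapply(group$recordings, function(r) r$samples[, sel, drop = FALSE])
  D <- nrow(X[[1]])
  if (!any_masked) {
    n <- length(sel)
    if (n < 2L) stop("span has fewer than 2 valid samples")
    # moment identity: cov = (X X' - n mu mu') / (n - 1), no centering copies
    S <- X[[1]]
    for (k in 2:N) S <- S + X[[k]]
    Rw <- matrix(0, D, D)
    for (k in seq_len(N)) {
      mu <- rowMeans(X[[k]])
      Rw <- Rw + (tcrossprod(X[[k]]) - n * tcrossprod(mu)) / (n - 1)
    }
    muS <- rowMeans(S)
    Rb <- (tcrossprod(S) - n * tcrossprod(muS)) / (n - 1) - Rw
  } else {
    V <- lapply(group$recordings, function(r) sample_valid(r)[sel])
    A <- Map(function(x, v) {
      if (sum(v) < 2L) stop("span has fewer than 2 valid samples")
      x - rowMeans(x[, v, drop = FALSE])
    }, X, V)
    Rw <- matrix(0, D, D); Rb <- matrix(0, D, D)
    for (k in seq_len(N)) for (l in seq_len(N)) {
      v <- V[[k]] & V[[l]]
      nv <- sum(v)
      if (nv < 2L) stop("span has fewer than 2 pairwise-valid samples")
      Rkl <- tcrossprod(A[[k]][, v, drop = FALSE], A[[l]][, v, drop = FALSE]) /
        (nv - 1)
      if (k == l) Rw <- Rw + Rkl else Rb <- Rb + Rkl
    }
  }
  Rb <- (Rb + t(Rb)) / 2
  list(Rw = Rw, Rb = Rb, n = N)
}

#' Fit correlated components maximizing between/within covariance ratio
#'
#' Solves the generalized eigenproblem
#' `Rb v = mu (Rw + lambda * (tr(Rw)/D) * I) v` and orders components by
#' their inter-subject correlation
#' `ISC_i = v_i' Rb v_i / ((N - 1) v_i' Rw v_i)` (non-increasing). Under this
#' `(N - 1)` normalization, N identical subjects give `ISC_1 = 1`. Weight
#' signs are fixed so the largest-magnitude weight is positive; forward
#' models (scalp topographies) are `A = Rw W (W' Rw W)^{-1}`.
#'
#' @param Rw,Rb pooled covariances from [pooled_covariances()].
#' @param n_subjects number of subjects pooled into `Rw`, `Rb`.
#' @param n_components number of components to retain (default all).
#' @param lambda shrinkage (diagonal loading relative to the mean eigenvalue
#'   of `Rw`); default 0.1. Window-level covariances are rank-deficient for
#'   short windows without it.
#' @return object of class `cca_model` with `weights`, `forward`, `isc`
#'   (retained components), `isc_all`, `Rw`, `Rb`, `n_subjects`, `lambda`.
#' @export
fit_cca <- function(Rw, Rb, n_subjects, n_components = NULL, lambda = 0.1) {
  if (!all(is.finite(Rw)) || !all(is.finite(Rb)))
    stop("non-finite covariance input")
  if (lambda < 0) stop("lambda must be >= 0")
  D <- nrow(Rw)
  if (is.null(n_components)) n_components <- D
  Rreg <- Rw + lambda * (sum(diag(Rw)) / D) * diag(D)
  U <- tryCatch(chol(Rreg), error = function(e)
    chol(Rreg + 1e-10 * sum(diag(Rreg)) / D * diag(D)))
  Wi <- backsolve(U, diag(D))          # Rreg^{-1/2} (upper-triangular inverse)
  M <- t(Wi) %*% Rb %*% Wi
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  V <- Wi %*% eig$vectors
  num <- colSums(V * (Rb %*% V))
  den <- (n_subjects - 1) * colSums(V * (Rw %*% V))
  isc_all <- ifelse(abs(den) > 0, num / den, NA_real_)
  ord <- order(isc_all, decreasing = TRUE)
  V <- V[, ord, drop = FALSE]
  isc_all <- isc_all[ord]
  # unit-norm weights, largest-|w| entry positive
  V <- apply(V, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  K <- min(n_components, D)
  Wk <- V[, seq_len(K), drop = FALSE]
  G <- t(Wk) %*% Rw %*% Wk
  forward <- tryCatch(Rw %*% Wk %*% solve(G), error = function(e)
    Rw %*% Wk %*% solve(G + 1e-12 * mean(diag(G)) * diag(K)))
  rownames(Wk) <- rownames(forward) <- rownames(Rw)
  structure(list(weights = Wk, forward = forward, isc = isc_all[seq_len(K)],
                 isc_all = isc_all, Rw = Rw, Rb = Rb,
                 n_subjects = n_subjects, lambda = lambda),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model: %d channels, %d components, N = %d>\n",
              nrow(x$weights), ncol(x$weights), x$n_subjects))
  cat("  ISC:", paste(signif(x$isc, 4), collapse = " "), "\n")
  invisible(x)
}

#' Convenience wrapper: pooled covariances + component fit on a group
#'
#' @inheritParams pooled_covariances
#' @inheritParams fit_cca
#' @return a `cca_model`.
#' @export
fit_cca_group <- function(group, n_components = 3L, lambda = 0.1,
                          exclude_masked = TRUE) {
  cov <- pooled_covariances(group, exclude_masked = exclude_masked)
  fit_cca(cov$Rw, cov$Rb, cov$n, n_components = n_components, lambda = lambda)
}

#' Time-resolved inter-subject correlation
#'
#' For each window `w` of the grid,
#' `ISC_i(w) = v_i' Rb(w) v_i / ((N - 1) v_i' Rw(w) v_i)` using
#' window-local covariances and the fixed global weights of `model`. Windows
#' with more than 50% masked samples (averaged over subjects) yield `NA`.
#'
#' @param group aligned [group_recording()].
#' @param model a [fit_cca()] model fitted on the same group/band.
#' @param grid a [window_grid()].
#' @param components component indices to evaluate (default 1).
#' @return list of `isc_series` objects (one per component), each with
#'   `component`, `band`, `values`, `grid`. A single component is returned
#'   unwrapped.
#' @export
isc_timecourse <- function(group, model, grid, components = 1L) {
  stopifnot(inherits(group, "group_recording"), inherits(model, "cca_model"),
            inherits(grid, "window_grid"))
  fs <- group$sample_rate
  gs <- grid_samples(grid, fs)
  n_tot <- ncol(group$recordings[[1]]$samples)
  if (any(gs$start + gs$len - 1L > n_tot)) stop("window outside recording span")
  N <- n_subjects(group)
  any_masked <- any(vapply(group$recordings, has_mask, logical(1)))
  V <- if (any_masked) do.call(rbind, lapply(group$recordings, sample_valid))
  band_name <- if (!is.null(group$recordings[[1]]$band))
    group$recordings[[1]]$band$name else NA_character_
  out <- vector("list", length(components))
  for (ci in seq_along(components)) {
    comp <- components[ci]
    v <- model$weights[, comp]
    Y <- do.call(rbind, lapply(group$recordings, function(r)
      as.numeric(v %*% r$samples)))
    nw <- grid$n_windows
    rw <- numeric(nw); rb <- numeric(nw)
    if (!any_masked) {
      # sum-channel identity: sum_{k != l} cov_kl = cov of Z = sum_k y_k
      # minus the within-subject part, needing only 2N + 2 windowed sums
      L <- gs$len
      Z <- colSums(Y)
      Sz <- wsum(Z, gs$start, L)
      Pzz <- wsum(Z^2, gs$start, L)
      tot <- (Pzz - Sz^2 / L) / (L - 1)
      for (k in seq_len(N)) {
        Sk <- wsum(Y[k, ], gs$start, L)
        Pkk <- wsum(Y[k, ]^2, gs$start, L)
        rw <- rw + (Pkk - Sk^2 / L) / (L - 1)
      }
      rb <- tot - rw
      frac_valid <- rep(1, nw)
    } else {
      frac_valid <- numeric(nw)
      for (k in seq_len(N)) {
        vk <- V[k, ]
        nk <- wsum(vk, gs$start, gs$len)
        frac_valid <- frac_valid + nk / gs$len / N
        Sk <- wsum(Y[k, ] * vk, gs$start, gs$len)
        Pkk <- wsum(Y[k, ]^2 * vk, gs$start, gs$len)
        rw <- rw + ifelse(nk > 1, (Pkk - Sk^2 / pmax(nk, 2)) / pmax(nk - 1, 1), NA)
        if (k < N) for (l in (k + 1L):N) {
          vkl <- vk & V[l, ]
          nkl <- wsum(vkl, gs$start, gs$len)
          Sk2 <- wsum(Y[k, ] * vkl, gs$start, gs$len)
          Sl2 <- wsum(Y[l, ] * vkl, gs$start, gs$len)
          Pkl <- wsum(Y[k, ] * Y[l, ] * vkl, gs$start, gs$len)
          rb <- rb + ifelse(nkl > 1,
                            2 * (Pkl - Sk2 * Sl2 / pmax(nkl, 2)) / pmax(nkl - 1, 1),
                            NA)
        }
      }
    }
    vals <- rb / ((N - 1) * rw)
    vals[frac_valid < 0.5] <- NA_real_
    out[[ci]] <- structure(list(component = comp, band = band_name,
                                values = vals, grid = grid),
                           class = "isc_series")
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' @export
print.isc_series <- function(x, ...) {
  cat(sprintf("<isc_series: C%d %s, %d windows, median %.4f>\n", x$component,
              x$band, length(x$values), stats::median(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.isc_series <- function(x, ...) {
  data.frame(band = x$band, component = x$component,
             window_start_s = x$grid$starts, isc = x$values)
}

#' Percentage of group covariance explained per component
#'
#' `pct_i = 100 * max(ISC_i, 0) / sum_j max(ISC_j, 0)` over the full
#' component set of the model.
#'
#' @param model a [fit_cca()] model.
#' @return numeric vector of percentages (sums to 100).
#' @export
explained_covariance <- function(model) {
  pos <- pmax(model$isc_all, 0)
  tot <- sum(pos, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("explained covariance undefined: all component ISC <= 0")
  100 * pos / tot
}
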