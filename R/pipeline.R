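#' Run configuration for the full pipeline
#'
#' Bundles the analysis parameters, with defaults matching the study
#' conventions: 5 s windows with 80% overlap, 1000 surrogate iterations,
#' 95th-percentile threshold, Granger lags 1-15 s, electrodes C3/C4/Cz and
#' O1/Oz/O2.
#'
#' @param sim a [sim_config()] describing the synthetic input.
#' @param bands named list of [band_spec()] (default [canonical_bands()]).
#' @param window_length,window_hop window grid in seconds.
#' @param iterations surrogate iterations.
#' @param level percentile threshold.
#' @param lags Granger lags.
#' @param lambda CCA shrinkage.
#' @param electrodes PLV electrodes (must exist among simulated channel
#'   labels; default first six channels when the canonical 10/10 names are
#'   absent).
#' @param assume_aligned skip photoresistor alignment.
#' @param seed global seed.
#' @param out_dir output directory for tables and the manifest (created);
#'   `NULL` for no file output.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), bands = canonical_bands(),
                       window_length = 5, window_hop = 1,
                       iterations = 1000L, level = 95, lags = 1:15,
                       lambda = 0.1, electrodes = NULL,
                       assume_aligned = FALSE, seed = 1L, out_dir = NULL) {
  structure(list(sim = sim, bands = bands, window_length = window_length,
                 window_hop = window_hop, iterations = as.integer(iterations),
                 level = level, lags = lags, lambda = lambda,
                 electrodes = electrodes, assume_aligned = assume_aligned,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every config key mirrors a [run_config()] argument; the `sim` block maps
#' onto [sim_config()] (its `band` entry as `list(name, low, high)`).
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$band))
    sim_args$band <- band_spec(sim_args$band$name, sim_args$band$low,
                               sim_args$band$high)
  y$sim <- do.call(sim_config, sim_args)
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full audience-synchrony analysis end to end
#'
#' Sequences simulate -> preprocess (band-pass, outlier zeroing, common
#' average reference) -> photoresistor alignment -> correlated components
#' and time-resolved ISC per band -> circular-shift null and cluster
#' correction -> features -> Granger scan -> PLV and band power, and writes
#' tidy CSV tables plus a JSON manifest (stage list, seed, per-file
#' checksums) when `out_dir` is set. Determinism: identical seed, identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return list with per-stage results and `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  log_msg <- function(fmt, ...) message(sprintf(fmt, ...))
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  sim <- run_stage("sim", simulate_audience(config$sim))
  group_raw <- sim$group
  truth <- sim$truth

  aligned <- run_stage("align", {
    if (config$assume_aligned || all(truth$device_offsets == 0)) {
      log_msg("align: skipped (assume_aligned or zero offsets)")
      group_raw$aligned <- TRUE
      group_raw
    } else {
      traces <- simulate_photoresistor(config$sim)
      onsets <- lapply(traces, detect_light_onset, rate = config$sim$sample_rate)
      g <- align_recordings(group_raw, onsets)
      err <- attr(g, "offsets") - truth$device_offsets
      log_msg("align: max residual offset %.1f ms",
              1000 * max(abs(err - mean(err))))
      g
    }
  })

  dur <- rec_duration(aligned$recordings[[1]])
  grid <- window_grid(dur, config$window_length, config$window_hop)

  per_band <- run_stage("preprocess+isc", {
    lapply(config$bands, function(band) {
      g <- group_map(aligned, function(r) {
        r <- bandpass_filter(r, band)
        r <- zero_outliers(r)
        common_average_reference(r)
      })
      frac <- mean(vapply(g$recordings, function(r) mean(r$mask), numeric(1)))
      log_msg("band %s: mean zeroed fraction %.3f%%", band$name, 100 * frac)
      model <- fit_cca_group(g, n_components = 3L, lambda = config$lambda)
      series <- isc_timecourse(g, model, grid, components = 1L)
      list(group = g, model = model, series = series,
           explained = explained_covariance(model))
    })
  })

  nulls <- run_stage("surrogate", {
    lapply(per_band, function(b)
      null_isc_distribution(b$group, grid, iterations = config$iterations,
                            seed = config$seed, level = config$level,
                            lambda = config$lambda))
  })
  clusters <- run_stage("clusters", {
    cs <- significant_clusters(lapply(per_band, `[[`, "series"), nulls)
    log_msg("clusters: %d found, %d significant (size threshold %g)",
            nrow(cs$clusters), sum(cs$clusters$significant), cs$size_threshold)
    cs
  })

  feats <- run_stage("features",
                     simulate_features(config$sim, truth, n_independent = 5L))

  scan <- run_stage("granger", {
    isc1 <- per_band[[1]]$series$values
    isc1 <- isc1[seq_len(min(length(isc1), config$sim$duration))]
    granger_scan(isc1, feats, lags = config$lags, auto_difference = TRUE)
  })

  plv_power <- run_stage("plv+power", {
    labs <- aligned$recordings[[1]]$channel_labels
    electrodes <- config$electrodes %||% labs[seq_len(min(6L, length(labs)))]
    half <- dur / 2
    sections <- data.frame(label = c("first_half", "second_half"),
                           start = c(0, half), end = c(half, dur))
    plv <- section_plv(per_band[[1]]$group, sections, electrodes = electrodes)
    pow <- do.call(rbind, lapply(aligned$recordings, function(r)
      rbind(welch_band_power(r, config$bands[[1]]),
            welch_band_power(r, config$bands[["alpha"]] %||% config$bands[[1]]))))
    list(plv = plv, power = power_outlier_filter(pow))
  })

  files <- character(0)
  if (!is.null(out_dir)) {
    isc_df <- do.call(rbind, lapply(per_band, function(b)
      as.data.frame(b$series)))
    write_table(isc_df, out_dir, "isc_timecourse.csv")
    topo <- do.call(rbind, lapply(names(per_band), function(nm)
      data.frame(band = nm,
                 channel = rownames(per_band[[nm]]$model$forward),
                 forward_c1 = per_band[[nm]]$model$forward[, 1])))
    write_table(topo, out_dir, "topographies.csv")
    write_table(clusters$clusters, out_dir, "clusters.csv")
    write_table(as.data.frame(scan), out_dir, "granger_scan.csv")
    write_table(plv_power$plv, out_dir, "plv.csv")
    write_table(plv_power$power, out_dir, "band_power.csv")
    feat_df <- do.call(rbind, lapply(feats, as.data.frame))
    write_table(feat_df, out_dir, "features.csv")
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  }
  manifest <- list(package_version = as.character(utils::packageVersion("audiencesync")),
                   seed = config$seed, stages = stages,
                   checksums = if (length(files))
                     as.list(tools::md5sum(files)) else list())
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  list(truth = truth, bands = per_band, nulls = nulls, clusters = clusters,
       features = feats, granger = scan, plv = plv_power$plv,
       power = plv_power$power, manifest = manifest)
}

#' Rank agreement between two continuous rating series
#'
#' Smooths both series with a centered rolling median (default 180 s) and
#' reports their Spearman rank correlation.
#'
#' @param series_a,series_b numeric series on a common clock.
#' @param smooth smoothing window in seconds (default 180).
#' @param rate series rate in Hz (default 1).
#' @return Spearman rho.
#' @export
rating_agreement <- function(series_a, series_b, smooth = 180, rate = 1) {
  n <- min(length(series_a), length(series_b))
  ok <- stats::complete.cases(series_a[seq_len(n)], series_b[seq_len(n)])
  if (sum(ok) < 10L) stop("need at least 10 common points")
  a <- rolling_median(series_a[seq_len(n)][ok], smooth, rate)
  b <- rolling_median(series_b[seq_len(n)][ok], smooth, rate)
  stats::cor(a, b, method = "spearman")
}
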