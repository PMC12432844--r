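#!/usr/bin/env Rscript
# Delta-band pairwise phase locking for contrasting sections and Welch band
# power per subject, with the 4 SD power outlier filter.
source("analysis/00_config.R")

sim <- simulate_audience(CFG)
photo <- simulate_photoresistor(CFG)
aligned <- align_recordings(sim$group,
                            lapply(photo, detect_light_onset,
                                   rate = CFG$sample_rate))
dur <- rec_duration(aligned$recordings[[1]])
gd <- group_map(aligned, bandpass_filter, band = BANDS$delta)

# high- vs low-engagement sections from the ground-truth gain
gain <- sim$truth$gain
sec_len <- 120
starts <- seq(0, CFG$duration - sec_len, by = 30)
sec_gain <- vapply(starts, function(s) mean(gain[(s + 1):(s + sec_len)]),
                   numeric(1))
sections <- data.frame(
  label = c("low_engagement", "high_engagement"),
  start = c(starts[which.min(sec_gain)], starts[which.max(sec_gain)]))
sections$end <- pmin(sections$start + sec_len, dur)
cat(sprintf("Sections: low engagement %g-%g s (mean gain %.2f), high %g-%g s (mean gain %.2f)\n",
            sections$start[1], sections$end[1], min(sec_gain),
            sections$start[2], sections$end[2], max(sec_gain)))

electrodes <- aligned$recordings[[1]]$channel_labels[1:6]
plv <- section_plv(gd, sections, electrodes = electrodes)
agg <- aggregate(plv ~ section, plv, mean)
print(agg)
# summarize per pair x electrode x section (the raw per-window table is large)
pair_sum <- aggregate(plv ~ section + subj_j + subj_k + electrode + region,
                      plv, function(v) mean(v, na.rm = TRUE))
write.csv(pair_sum, file.path(RESULTS, "plv_sections.csv"), row.names = FALSE)

pow <- do.call(rbind, lapply(aligned$recordings, function(r)
  rbind(welch_band_power(r, BANDS$delta),
        welch_band_power(r, BANDS$alpha))))
pow_f <- power_outlier_filter(pow)
cat(sprintf("Band power rows: %d kept, %d dropped as >4 SD outliers.\n",
            nrow(pow_f), attr(pow_f, "n_dropped")))
write.csv(pow_f, file.path(RESULTS, "band_power.csv"), row.names = FALSE)
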