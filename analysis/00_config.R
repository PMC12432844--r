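# Shared configuration for the analysis scripts.
#
# One synthetic "performance evening": a 16-person audience wearing 32-channel
# mobile EEG at 250 Hz for 5 minutes, with a slow engagement gain driven by a
# 1 Hz performance feature at a 3 s lag, device clock offsets, artifact
# bursts, and a photoresistor blackout for alignment. Everything downstream
# derives deterministically from SEED.

library(audiencesync)

SEED <- 20260922L
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

CFG <- sim_config(
  n_subjects = 16L, n_channels = 32L, sample_rate = 250, duration = 300,
  band = canonical_bands()$delta, snr = 0.1,
  artifact_rate = 2, artifact_scale = 8,
  coupling_lag = 3, coupling_beta = 1,
  blackout_time = 12, seed = SEED)

BANDS <- canonical_bands()
GRID_LEN <- 5    # seconds
GRID_HOP <- 1    # seconds (80% overlap)
SURROGATES <- 200L   # scaled from the 1000 used at full scale
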