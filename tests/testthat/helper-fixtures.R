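# Small in-code fixtures shared across test files.

# A group of subjects observing a common band-limited source plus noise.
make_shared_group <- function(n_subj = 4, n_ch = 4, dur = 30, fs = 250,
                              snr = 1, seed = 42, aligned = TRUE) {
  set.seed(seed)
  n <- dur * fs
  bf <- signal::butter(5, c(1, 4) / (fs / 2), "pass")
  src <- signal::filtfilt(bf, rnorm(n))
  src <- src / sd(src)
  recs <- lapply(seq_len(n_subj), function(k) {
    m <- rnorm(n_ch); m <- m / sqrt(sum(m^2))
    x <- snr * outer(m, src) + matrix(rnorm(n_ch * n), n_ch)
    recording(x, fs, subject_id = sprintf("S%02d", k))
  })
  group_recording(recs, aligned = aligned)
}

# Identical-subjects group (perfect synchrony case).
make_identical_group <- function(n_subj = 3, n_ch = 4, dur = 20, fs = 250,
                                 seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n_ch * dur * fs), n_ch)
  group_recording(lapply(seq_len(n_subj), function(k)
    recording(x, fs, subject_id = sprintf("S%02d", k))), aligned = TRUE)
}

sine_recording <- function(freq, dur = 10, fs = 250, amp = 1, n_ch = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  recording(matrix(rep(amp * sin(2 * pi * freq * t), n_ch), nrow = n_ch,
                   byrow = TRUE), fs)
}
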