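Package: audiencesync
Title: Inter-Brain Synchrony Analysis for Naturalistic Audience EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying collective neural engagement in audiences
    of naturalistic performances from multi-subject mobile EEG. Implements
    correlated-components inter-subject correlation (ISC) with time-resolved
    windows, circular-shift surrogate nulls with cluster-based
    multiple-comparison correction, resting-state baseline contrasts,
    pairwise phase-locking values, Welch band power, continuous
    performance-feature extraction (audio energy, pulse clarity, movement
    acceleration, dancer distance, luminance, continuous ratings,
    respiration synchrony), augmented Dickey-Fuller stationarity screening,
    and pairwise Granger-causality scans from features to the synchrony time
    course. A synthetic multi-subject generator with known ground truth
    (shared band-limited source, slow engagement gain, spatially correlated
    noise, artifact bursts, device clock offsets, photoresistor blackout
    traces) makes the full pipeline testable without recorded audience data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    yaml
Config/testthat/edition: 3
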