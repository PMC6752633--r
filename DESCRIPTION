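Package: ppgcohort
Title: Co-Registered ECG and Finger/Toe Photoplethysmography Feature
    Extraction and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of co-registered single-lead ECG and
    two-site (finger, toe) photoplethysmography (PPG) recordings:
    channel-specific zero-phase Butterworth band-limiting, derivative-filter
    QRS detection with adaptive thresholding, per-beat PPG fiducial
    extraction (onset, rising point, systolic peak, dicrotic notch,
    diastolic peak), latency features (PAT, PTT, SPTT, DPTT) and waveform
    area morphology (S1-S4, A1, A2, IPA, S2/S1), per-subject aggregation
    with height normalization, and a cohort-level statistical battery of
    pairwise linear regressions and Student's t-tests under a dual
    significance gate (p < alpha and r-squared above a floor).  A seeded
    synthetic-cohort generator produces fully annotated ECG+PPG recordings
    with programmable sex, height and heart-rate effects for validation and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
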