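# Shared fixtures, all built in code at test time.

# Short, noise-free cohort configuration for deterministic waveform tests.
clean_config <- function(n_subjects = 2, duration = 20, seed = 101, ...) {
  cohort_config(n_subjects = n_subjects, duration = duration, seed = seed,
                noise_sd = 0, wander_amp = 0, powerline_amp = 0, ...)
}

# Raised-cosine spike train: an ECG-like fixture independent of the
# package's own renderer.
spike_train <- function(centers_s, fs, dur_s, width_s = 0.024, amp = 1) {
  n <- round(fs * dur_s)
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (c0 in centers_s) {
    idx <- which(abs(t - c0) <= width_s / 2)
    sig[idx] <- sig[idx] + amp * 0.5 * (1 + cos(2 * pi * (t[idx] - c0) / width_s))
  }
  sig
}

# Match each truth time (seconds) to the nearest detection; returns signed
# errors in ms (NA where no detection within `tol_s`).
match_events <- function(truth_s, detected_s, tol_s = 0.05) {
  vapply(truth_s, function(tt) {
    d <- detected_s - tt
    j <- which.min(abs(d))
    if (length(j) && abs(d[j]) <= tol_s) d[j] * 1000 else NA_real_
  }, numeric(1))
}

# Pull one site's beat fiducials for a clean recording, alongside matched
# ground-truth landmark times.  Truth beats whose cycle extends beyond the
# segmented range (before the first / after the last detected R peak) are
# not observable and are excluded from the comparison.
fiducial_errors_ms <- function(gen, site, fs) {
  rec <- gen$recording
  filt <- preprocess_recording(rec)
  peaks <- detect_r_peaks(filt$ecg, fs)
  fids <- extract_beat_fiducials(filt[[paste0("ppg_", site)]], peaks, fs)
  fids <- fids[fids$valid, ]
  truth <- gen$truth$beats
  last_t <- (max(peaks$r_indices) - 1) / fs
  first_t <- (min(peaks$r_indices) - 1) / fs
  truth <- truth[truth$site == site & truth$r_time >= first_t - 0.05 &
                   truth$end_time <= last_t + 0.05, ]
  idx_s <- function(i) (i[!is.na(i)] - 1) / fs
  cols <- c(onset = "onset_index", rising = "rising_index",
            systolic = "systolic_index", notch = "notch_index",
            diastolic = "diastolic_index")
  out <- lapply(names(cols), function(lm) {
    match_events(truth[[paste0(lm, "_time")]], idx_s(fids[[cols[lm]]]))
  })
  names(out) <- names(cols)
  out
}
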