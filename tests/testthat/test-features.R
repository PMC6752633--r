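mk_fid <- function(onset, rising, systolic, notch, end, r = 1L, dia = NA) {
  tibble::tibble(beat_id = 1L, r_index = as.integer(r),
                 onset_index = as.integer(onset),
                 rising_index = as.integer(rising),
                 systolic_index = as.integer(systolic),
                 notch_index = as.integer(notch),
                 diastolic_index = as.integer(dia),
                 end_index = as.integer(end),
                 valid = TRUE, reject_reason = NA_character_)
}

test_that("latencies are plain index arithmetic in milliseconds", {
  f <- mk_fid(onset = 1181, rising = 1221, systolic = 1301, notch = 1400,
              end = 1800, r = 1001, dia = 1600)
  lat <- compute_latencies(f, fs = 1000)
  expect_equal(lat$pat, 180)
  expect_equal(lat$ptt, 220)
  expect_equal(lat$sptt, 300)
  expect_equal(lat$dptt, 599)

  # degenerate: onset = rising = systolic collapses all three latencies
  g <- mk_fid(onset = 1100, rising = 1100, systolic = 1100, notch = 1200,
              end = 1500, r = 1000)
  lg <- compute_latencies(g, fs = 1000)
  expect_equal(lg$pat, lg$ptt)
  expect_equal(lg$ptt, lg$sptt)

  bad <- f
  bad$valid <- FALSE
  expect_error(compute_latencies(bad, 1000), "invalid beat")
})

test_that("rectangle-with-notch fixture yields IPA exactly 1/3", {
  ppg <- c(0, rep(1, 10), 0)
  f <- mk_fid(onset = 1, rising = 2, systolic = 3, notch = 9, end = 12)
  ar <- compute_areas(ppg, f, fs = 1)
  expect_identical(ar$a1, ar$s1 + ar$s2 + ar$s3)
  expect_equal(ar$ipa, 1 / 3, tolerance = 1e-15)
})

test_that("areas equal hand-computed trapezoids and their ratios follow", {
  # ramp up 0,2,6 then plateau to notch then tail; dt = 1 s
  ppg <- c(0, 2, 6, 6, 6, 3, 2, 1, 0)
  f <- mk_fid(onset = 1, rising = 2, systolic = 3, notch = 6, end = 9)
  ar <- compute_areas(ppg, f, fs = 1)
  expect_equal(ar$s1, 1)            # (0+2)/2
  expect_equal(ar$s2, 4)            # (2+6)/2
  expect_equal(ar$s3, 6 + 6 + 4.5)  # two flat panels + drop to 3
  expect_equal(ar$s4, 2.5 + 1.5 + 0.5)
  expect_equal(ar$s2_over_s1, 4)
  expect_equal(ar$ipa, ar$a2 / ar$a1)

  # scaling the signal leaves both ratios unchanged
  ar2 <- compute_areas(5 * ppg, f, fs = 1)
  expect_equal(ar2$ipa, ar$ipa)
  expect_equal(ar2$s2_over_s1, ar$s2_over_s1)
  expect_equal(ar2$s1, 5 * ar$s1)
})

test_that("pipeline areas are additive and match fine-grid quadrature", {
  cfg <- clean_config(n_subjects = 2, duration = 12, seed = 29)
  seeds <- ppgcohort:::derive_seeds(cfg$seed, 2)
  subj <- generate_subject(cfg, seeds[1], "S001")
  gen <- generate_recording(subj, cfg, seeds[2])
  rec <- gen$recording
  fs <- cfg$fs
  truth <- gen$truth$beats
  truth <- truth[truth$site == "finger" & truth$end_time < cfg$duration, ]
  idx <- function(t) as.integer(round(t * fs) + 1L)
  fids <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    mk_fid(onset = idx(truth$onset_time[i]), rising = idx(truth$rising_time[i]),
           systolic = idx(truth$systolic_time[i]),
           notch = idx(truth$notch_time[i]), end = idx(truth$end_time[i]),
           r = idx(truth$r_time[i]), dia = idx(truth$diastolic_time[i]))
  }))
  fids$beat_id <- seq_len(nrow(fids))
  ar <- compute_areas(rec$ppg_finger, fids, fs)

  # additivity against the total onset-to-end trapezoid
  for (i in seq_len(nrow(fids))) {
    i0 <- fids$onset_index[i]; i1 <- fids$end_index[i]
    base <- rec$ppg_finger[fids$onset_index[i]]
    total <- pracma::trapz(seq(0, by = 1 / fs, length.out = i1 - i0 + 1),
                           rec$ppg_finger[i0:i1] - base)
    s_sum <- ar$s1[i] + ar$s2[i] + ar$s3[i] + ar$s4[i]
    expect_lt(abs(s_sum - total) / abs(total), 1e-9)
    expect_lt(abs((ar$a1[i] + ar$a2[i]) - total) / abs(total), 1e-9)
  }

  # oracle: fine-grid quadrature of the analytic two-lobe pulse, with the
  # subject's shape parameters read off the rendered clean signal
  lm1 <- truth[3, ]
  notch_level <- rec$ppg_finger[idx(lm1$notch_time)]
  dia_amp <- rec$ppg_finger[idx(lm1$diastolic_time)] - notch_level
  fine_area <- function(t0, t1, lm) {
    tt <- seq(t0, t1, length.out = 20001)
    y <- ppgcohort:::ppg_pulse_eval(
      tt - lm$onset_time,
      w1 = lm$rising_time - lm$onset_time,
      w2 = lm$systolic_time - lm$rising_time,
      w3 = lm$notch_time - lm$systolic_time,
      w4 = lm$diastolic_time - lm$notch_time,
      w5 = lm$end_time - lm$diastolic_time,
      notch_level = notch_level, dia_amp = dia_amp)
    pracma::trapz(tt, y)
  }
  # oracle boundaries at the sampled landmark times, so the check isolates
  # quadrature accuracy from sub-sample boundary quantization
  grid_t <- function(t) (idx(t) - 1) / fs
  i <- 3
  s1_fine <- fine_area(grid_t(truth$onset_time[i]),
                       grid_t(truth$rising_time[i]), truth[i, ])
  s2_fine <- fine_area(grid_t(truth$rising_time[i]),
                       grid_t(truth$systolic_time[i]), truth[i, ])
  s3_fine <- fine_area(grid_t(truth$systolic_time[i]),
                       grid_t(truth$notch_time[i]), truth[i, ])
  s4_fine <- fine_area(grid_t(truth$notch_time[i]),
                       grid_t(truth$end_time[i]), truth[i, ])
  expect_lt(abs(ar$s1[i] - s1_fine) / s1_fine, 0.01)
  expect_lt(abs(ar$s2[i] - s2_fine) / s2_fine, 0.01)
  expect_lt(abs(ar$s3[i] - s3_fine) / s3_fine, 0.01)
  expect_lt(abs(ar$s4[i] - s4_fine) / s4_fine, 0.01)
})

test_that("subject aggregation computes BMI, normalization, and gating", {
  subj <- tibble::tibble(subject_id = "S1", sex = "male", age = 30,
                         height = 1.75, weight = 70, smoker = FALSE,
                         hypertensive = FALSE, sbp = 120, dbp = 80)
  one_site <- tibble::tibble(beat_id = 1:6, pat = 180, ptt = 350, sptt = 300,
                             dptt = NA_real_, s1 = 1, s2 = 2, s3 = 3, s4 = 2,
                             a1 = 6, a2 = 2, ipa = 1 / 3, s2_over_s1 = 2,
                             area_valid = TRUE)
  hr <- list(hr_mean = 65, hr_variance = 4)
  rec <- aggregate_subject(list(finger = one_site, toe = one_site), hr, subj)
  expect_equal(rec$bmi, 70 / 1.75^2, tolerance = 1e-12)
  expect_equal(rec$pat_finger, 180)       # identical beats: mean = value
  expect_equal(rec$ptt_norm_finger, 350 / 1.75)
  expect_equal(rec$ptt_norm_finger, 200)
  expect_equal(rec$n_beats_finger, 6L)
  expect_equal(rec$sex_male, 1L)

  few <- one_site[1:3, ]
  excluded <- aggregate_subject(list(finger = few, toe = one_site), hr, subj,
                                min_beats = 5)
  expect_equal(nrow(excluded), 0)
  expect_match(attr(excluded, "exclusion"), "excluded")
})

test_that("latencies are invariant under a uniform time shift", {
  f <- mk_fid(onset = 1181, rising = 1221, systolic = 1301, notch = 1400,
              end = 1800, r = 1001)
  shifted <- f
  for (col in c("r_index", "onset_index", "rising_index", "systolic_index",
                "notch_index", "end_index")) {
    shifted[[col]] <- shifted[[col]] + 500L
  }
  expect_equal(compute_latencies(f, 1000)[, c("pat", "ptt", "sptt")],
               compute_latencies(shifted, 1000)[, c("pat", "ptt", "sptt")])
})
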