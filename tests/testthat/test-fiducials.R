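mk_peaks <- function(idx, fs = 1000) ppgcohort:::new_r_peak_series(idx, fs)

test_that("segmentation is a half-open partition anchored at R peaks", {
  ppg <- rnorm(3000)
  w <- segment_beats(ppg, mk_peaks(c(100L, 1100L, 2100L)))
  expect_length(w, 2)
  expect_equal(w[[1]]$start, 100)
  expect_equal(w[[1]]$end, 1099)
  expect_equal(w[[2]]$start, 1100)
  expect_equal(w[[2]]$end, 2099)
  expect_equal(w[[1]]$signal, ppg[100:1099])
  expect_error(segment_beats(ppg, mk_peaks(100L)), "at least 2")
})

test_that("each window of a clean recording contains one programmed pulse", {
  cfg <- clean_config(n_subjects = 2, duration = 12, seed = 71)
  res <- generate_cohort(cfg)
  rec <- preprocess_recording(res$recordings[[1]])
  peaks <- detect_r_peaks(rec$ecg, rec$fs)
  w <- segment_beats(rec$ppg_finger, peaks)
  truth <- res$truth_beats
  onsets <- truth$onset_time[truth$site == "finger" &
                               truth$subject_id == "S001"]
  n_in <- vapply(w, function(win) {
    sum(onsets >= (win$start - 1) / rec$fs & onsets < win$end / rec$fs)
  }, numeric(1))
  expect_true(all(n_in == 1))
})

test_that("half-sine pulse rising from the window start is handled", {
  fs <- 1000
  x <- sin(pi * (0:499) / 999)        # rising half of a sine
  win <- list(beat_id = 1L, signal = x, start = 1L, end = 500L, r_index = 1L)
  f <- extract_fiducials(win, fs)
  expect_equal(f$rising_index, 1L)
  expect_equal(f$onset_index, f$rising_index)
  expect_false(f$valid)               # onset collides with the window start
})

test_that("monotonically decaying window is rejected with a reason", {
  win <- list(beat_id = 1L, signal = exp(-(0:799) / 200), start = 1L,
              end = 800L, r_index = 1L)
  f <- extract_fiducials(win, 1000)
  expect_false(f$valid)
  expect_false(is.na(f$reject_reason))
})

test_that("clean synthetic landmarks are recovered within 5 ms", {
  cfg <- clean_config(n_subjects = 2, duration = 15, seed = 83)
  seeds <- ppgcohort:::derive_seeds(cfg$seed, 2)
  subj <- generate_subject(cfg, seeds[1], "S001")
  gen <- generate_recording(subj, cfg, seeds[2])
  err <- fiducial_errors_ms(gen, "finger", cfg$fs)
  for (lm in c("onset", "rising", "systolic", "notch", "diastolic")) {
    e <- err[[lm]]
    expect_gt(mean(!is.na(e)), 0.95)
    expect_lt(mean(abs(e), na.rm = TRUE), 5)
    expect_lt(max(abs(e), na.rm = TRUE), 15)
  }
})

test_that("fiducial indices are invariant to amplitude scaling and offset", {
  cfg <- clean_config(n_subjects = 2, duration = 10, seed = 97)
  res <- generate_cohort(cfg)
  rec <- preprocess_recording(res$recordings[[1]])
  peaks <- detect_r_peaks(rec$ecg, rec$fs)
  f0 <- extract_beat_fiducials(rec$ppg_finger, peaks, rec$fs)
  f1 <- extract_beat_fiducials(3.7 * rec$ppg_finger + 11, peaks, rec$fs)
  for (col in c("onset_index", "rising_index", "systolic_index",
                "notch_index", "diastolic_index", "valid")) {
    expect_identical(f0[[col]], f1[[col]])
  }
})

test_that("ordering invariant holds on every valid extracted beat", {
  cfg <- cohort_config(n_subjects = 2, duration = 15, seed = 13)  # with noise
  res <- generate_cohort(cfg)
  rec <- preprocess_recording(res$recordings[[2]])
  peaks <- detect_r_peaks(rec$ecg, rec$fs)
  for (site in c("ppg_finger", "ppg_toe")) {
    f <- extract_beat_fiducials(rec[[site]], peaks, rec$fs)
    v <- f[f$valid, ]
    expect_gt(nrow(v), 5)
    expect_true(all(v$r_index < v$onset_index))
    expect_true(all(v$onset_index < v$rising_index))
    expect_true(all(v$rising_index <= v$systolic_index))
    expect_true(all(v$systolic_index < v$notch_index))
    with_dia <- !is.na(v$diastolic_index)
    expect_true(all(v$notch_index[with_dia] < v$diastolic_index[with_dia]))
    expect_true(all(v$systolic_index < v$end_index))
  }
})

test_that("quality policy drops invalid beats and masks sparse diastolic sites", {
  mk_beats <- function(valid, dia) {
    tibble::tibble(
      beat_id = seq_along(valid), r_index = 1L, onset_index = 10L,
      rising_index = 20L, systolic_index = 30L, notch_index = 40L,
      diastolic_index = ifelse(dia, 50L, NA_integer_), end_index = 100L,
      valid = valid,
      reject_reason = ifelse(valid, NA_character_, "notch_not_found"))
  }
  all_ok <- mk_beats(rep(TRUE, 10), rep(TRUE, 10))
  res <- apply_quality_policy(all_ok, "finger")
  expect_equal(nrow(res$beats), 10)
  expect_false(res$report$diastolic_masked)

  sparse <- mk_beats(rep(TRUE, 10), c(TRUE, rep(FALSE, 9)))  # 10% diastolic
  res2 <- apply_quality_policy(sparse, "toe")
  expect_true(res2$report$diastolic_masked)
  expect_true(all(is.na(res2$beats$diastolic_index)))
  expect_equal(res2$report$diastolic_rate, 0.1)

  mixed <- mk_beats(c(rep(TRUE, 6), rep(FALSE, 4)), rep(TRUE, 10))
  res3 <- apply_quality_policy(mixed, "finger")
  expect_equal(nrow(res3$beats), 6)
  expect_equal(res3$report$n_total, 10)

  empty <- apply_quality_policy(all_ok[0, ], "finger")
  expect_equal(empty$report$n_total, 0)
})
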