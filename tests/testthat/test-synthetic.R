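test_that("subject generation honors sex ratio, bounds, and determinism", {
  cfg <- cohort_config(n_subjects = 20, seed = 5, sex_ratio = 1.0)
  subs <- lapply(1:20, function(i) generate_subject(cfg, 1000 + i))
  expect_true(all(vapply(subs, function(s) s$sex, character(1)) == "male"))

  s1 <- generate_subject(cfg, 777, "X")
  s2 <- generate_subject(cfg, 777, "X")
  expect_identical(s1, s2)

  heights <- vapply(subs, function(s) s$height, numeric(1))
  expect_true(all(heights > 1.2 & heights < 2.2))
  weights <- vapply(subs, function(s) s$weight, numeric(1))
  expect_true(all(weights > 30 & weights < 200))

  bad <- cohort_config()
  bad$sex_ratio <- 2
  expect_error(ppgcohort:::validate_cohort_config(bad), "sex_ratio")
})

test_that("sampled heights recover the configured sex-specific means", {
  cfg <- cohort_config(n_subjects = 1000, seed = 11,
                       height_mean_male = 1.78, height_mean_female = 1.64,
                       height_sd = 0.07)
  seeds <- ppgcohort:::derive_seeds(cfg$seed, 1000)
  subs <- do.call(rbind, lapply(seq_len(1000), function(i)
    generate_subject(cfg, seeds[i], sprintf("S%04d", i))))
  for (sx in c("male", "female")) {
    h <- subs$height[subs$sex == sx]
    mu <- if (sx == "male") 1.78 else 1.64
    se <- 0.07 / sqrt(length(h))
    expect_lt(abs(mean(h) - mu), 3 * se)
  }
})

test_that("ground-truth landmarks are strictly ordered and reproducible", {
  cfg <- clean_config(n_subjects = 3, duration = 15, seed = 21)
  res1 <- generate_cohort(cfg)
  res2 <- generate_cohort(cfg)
  expect_identical(res1$recordings[[2]]$ppg_finger,
                   res2$recordings[[2]]$ppg_finger)
  expect_identical(res1$truth_subjects, res2$truth_subjects)
  expect_identical(res1$subjects$subject_id, c("S001", "S002", "S003"))
  expect_false(any(duplicated(res1$subjects$subject_id)))

  tb <- res1$truth_beats
  expect_true(all(tb$r_time < tb$onset_time))
  expect_true(all(tb$onset_time < tb$rising_time))
  expect_true(all(tb$rising_time < tb$systolic_time))
  expect_true(all(tb$systolic_time < tb$notch_time))
  expect_true(all(tb$notch_time < tb$diastolic_time))
  expect_true(all(tb$diastolic_time < tb$end_time))
})

test_that("truth-only cohorts match rendered cohorts at the same seed", {
  cfg <- clean_config(n_subjects = 4, duration = 15, seed = 33)
  full <- generate_cohort(cfg, render = TRUE)
  fast <- generate_cohort(cfg, render = FALSE)
  expect_null(fast$recordings)
  expect_identical(full$truth_subjects, fast$truth_subjects)
  expect_identical(full$truth_beats, fast$truth_beats)
})

test_that("clean-signal fiducials match ground truth within one sample", {
  cfg <- clean_config(n_subjects = 2, duration = 12, seed = 44)
  seeds <- ppgcohort:::derive_seeds(cfg$seed, 4)
  subj <- generate_subject(cfg, seeds[1], "S001")
  gen <- generate_recording(subj, cfg, seeds[2])
  fs <- cfg$fs
  for (site in c("finger", "toe")) {
    ppg <- gen$recording[[paste0("ppg_", site)]]
    tb <- gen$truth$beats
    tb <- tb[tb$site == site & tb$end_time < cfg$duration, ]
    for (i in seq_len(nrow(tb))) {
      # brute-force scan over the true pulse extent of the clean waveform
      i0 <- round(tb$onset_time[i] * fs) + 1L
      i1 <- round(tb$end_time[i] * fs) + 1L
      w <- ppg[i0:i1]
      rise_bf <- i0 + which.max(diff(w)) - 1L
      sys_bf <- i0 + which.max(w) - 1L
      seg_after <- w[(sys_bf - i0 + 1L):length(w)]
      maxima <- which(diff(sign(diff(seg_after))) < 0) + 1L
      dia_rel <- maxima[which.max(seg_after[maxima])]
      dia_bf <- sys_bf + dia_rel - 1L
      notch_bf <- sys_bf + which.min(ppg[sys_bf:dia_bf]) - 1L
      expect_lte(abs(rise_bf - (round(tb$rising_time[i] * fs) + 1L)), 1)
      expect_lte(abs(sys_bf - (round(tb$systolic_time[i] * fs) + 1L)), 1)
      expect_lte(abs(notch_bf - (round(tb$notch_time[i] * fs) + 1L)), 1)
      expect_lte(abs(dia_bf - (round(tb$diastolic_time[i] * fs) + 1L)), 1)
    }
  }
})

test_that("programmed sex effect appears in finger, not toe, ground truth", {
  cfg <- cohort_config(n_subjects = 120, seed = 55, duration = 10,
                       sex_ratio = 0.5,
                       height_mean_male = 1.71, height_mean_female = 1.71,
                       sex_effect_finger = 20, sex_effect_toe = 0)
  tt <- generate_cohort(cfg, render = FALSE)$truth_subjects
  male <- tt$sex_male == 1
  d_f <- mean(tt$ptt_finger[male]) - mean(tt$ptt_finger[!male])
  d_t <- mean(tt$ptt_toe[male]) - mean(tt$ptt_toe[!male])
  se_f <- sqrt(var(tt$ptt_finger[male]) / sum(male) +
                 var(tt$ptt_finger[!male]) / sum(!male))
  se_t <- sqrt(var(tt$ptt_toe[male]) / sum(male) +
                 var(tt$ptt_toe[!male]) / sum(!male))
  expect_lt(abs(d_f - 20), 3 * se_f)
  expect_lt(abs(d_t), 3 * se_t)
})

test_that("configured height slope and HR coupling are recoverable from truth", {
  cfg <- cohort_config(n_subjects = 500, seed = 66, duration = 10,
                       sex_effect_finger = 0, sex_effect_toe = 0,
                       height_mean_male = 1.71, height_mean_female = 1.71,
                       hr_ptt_coupling = -2, hr_sd = 10)
  tt <- generate_cohort(cfg, render = FALSE)$truth_subjects
  fit <- lm(ptt_finger ~ height + hr_mean, data = tt)
  slope <- coef(fit)["height"]
  se <- summary(fit)$coefficients["height", "Std. Error"]
  expect_lt(abs(slope - cfg$height_slope), 3 * se)

  # correlation implied by the linear Gaussian program
  r_obs <- cor(tt$hr_mean, tt$ptt_finger)
  var_hr_term <- (cfg$hr_ptt_coupling * cfg$hr_sd)^2
  var_tot <- var_hr_term + (cfg$height_slope * cfg$height_sd)^2 +
    cfg$ptt_subject_sd_finger^2
  r_implied <- cfg$hr_ptt_coupling * cfg$hr_sd / sqrt(var_tot)
  expect_lt(r_obs, 0)
  expect_lt(abs(r_obs - r_implied), 0.12)
})

test_that("degenerate configurations are rejected with the field named", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(notch_fraction = 1.2), "notch_fraction")
  expect_error(cohort_config(fs = -1), "fs")
  cfg <- clean_config(seed = 9)
  subj <- generate_subject(cfg, 1, "S1")
  short <- cfg
  short$duration <- 0.05
  expect_error(generate_recording(subj, short, 2), "duration")
})
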