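#' Cohort simulation configuration
#'
#' Builds and validates the full parameter set for the synthetic ECG+PPG
#' cohort generator.  Defaults encode the study conditions the pipeline is
#' designed around: an ~80-subject cohort of young adults (41 male / 39
#' female split), 1 kHz sampling, three-minute recordings, finger and toe
#' PPG channels whose programmed latencies scale with height, couple
#' negatively to heart rate, and carry a sex effect on the finger site only.
#'
#' All latencies are in milliseconds, heights in meters, rates in bpm,
#' amplitudes relative to a unit pulse.  `sex_effect_finger` /
#' `sex_effect_toe` are added to the male group's programmed pulse transit
#' time (PTT); the per-site programmed latencies of a subject are
#'
#' `PTT = base_ptt + sex_effect * male + height_slope * (height - height_ref)
#'        + hr_ptt_coupling * (HR - hr_mean) + N(0, ptt_subject_sd)`
#'
#' with `PAT = PTT - pat_ptt_gap` and `SPTT = PTT + ptt_sptt_gap` (the gaps
#' jittered per subject by `gap_sd` within hard physiologic bounds).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer root seed; every random draw in the cohort derives
#'   from it through per-subject substreams.
#' @param sex_ratio Fraction of male subjects in `[0, 1]`.
#' @param height_mean_male,height_mean_female Sex-specific mean height (m).
#' @param height_sd Height standard deviation (m).
#' @param height_ref Reference height (m) at which `base_ptt_*` applies.
#' @param base_ptt_finger,base_ptt_toe Baseline PTT per site (ms).
#' @param sex_effect_finger,sex_effect_toe Additive male-group PTT shift (ms).
#' @param height_slope PTT change per meter of height (ms/m).
#' @param hr_mean,hr_sd Between-subject heart-rate distribution (bpm).
#' @param hr_ptt_coupling PTT change per bpm of subject heart rate
#'   (ms/bpm, physiologically negative).
#' @param ptt_subject_sd_finger,ptt_subject_sd_toe Residual between-subject
#'   PTT spread per site (ms).  The toe default is larger: the longer,
#'   more heterogeneous arterial path to the lower limb carries more
#'   between-subject variability, which (together with the r-squared gate)
#'   is what keeps the height-mediated sex-to-toe-latency correlation
#'   below significance while the finger sex effect stays detectable.
#' @param pat_ptt_gap Onset-to-rising-point delay (ms, > 0); PAT = PTT - gap.
#' @param ptt_sptt_gap Rising-point-to-systolic-peak delay (ms, > 0).
#' @param gap_sd Per-subject jitter of the two gaps (ms).
#' @param notch_fraction Dicrotic-notch position as a fraction of the pulse
#'   duration (onset to cycle end), in (0, 1).
#' @param dia_fraction Diastolic-peak position as a fraction of the
#'   notch-to-end interval, in (0, 1).
#' @param notch_level,notch_level_sd Notch amplitude (fraction of the unit
#'   systolic peak) and its per-subject jitter.
#' @param dia_amp_finger,dia_amp_toe,dia_amp_sd Diastolic-wave amplitude per
#'   site (above the notch level) and its per-subject jitter.
#' @param rr_jitter_sd Standard deviation of Gaussian jitter on log RR.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd Blood-pressure distribution (mmHg).
#' @param bp_missing Probability that a subject's SBP/DBP are absent.
#' @param noise_sd Broadband noise amplitude (relative to the unit pulse).
#' @param wander_amp Baseline-wander amplitude (relative).
#' @param powerline_amp 60 Hz interference amplitude (relative).
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (s).
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_subjects = 80,
                          seed = 1L,
                          sex_ratio = 41 / 80,
                          height_mean_male = 1.78,
                          height_mean_female = 1.64,
                          height_sd = 0.07,
                          height_ref = 1.71,
                          base_ptt_finger = 250,
                          base_ptt_toe = 350,
                          sex_effect_finger = 20,
                          sex_effect_toe = 0,
                          height_slope = 80,
                          hr_mean = 70,
                          hr_sd = 10,
                          hr_ptt_coupling = -1,
                          ptt_subject_sd_finger = 15,
                          ptt_subject_sd_toe = 55,
                          pat_ptt_gap = 40,
                          ptt_sptt_gap = 80,
                          gap_sd = 6,
                          notch_fraction = 0.35,
                          dia_fraction = 0.35,
                          notch_level = 0.40,
                          notch_level_sd = 0.05,
                          dia_amp_finger = 0.15,
                          dia_amp_toe = 0.08,
                          dia_amp_sd = 0.03,
                          rr_jitter_sd = 0.03,
                          sbp_mean = 119, sbp_sd = 11,
                          dbp_mean = 77, dbp_sd = 9,
                          bp_missing = 0.15,
                          noise_sd = 0.02,
                          wander_amp = 0.05,
                          powerline_amp = 0.01,
                          fs = 1000,
                          duration = 180) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid cohort configuration: field '%s' %s", field, why),
           call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$n_subjects) && cfg$n_subjects >= 2, "n_subjects", "must be >= 2")
  chk(num1(cfg$seed), "seed", "must be a finite number")
  chk(num1(cfg$sex_ratio) && cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1,
      "sex_ratio", "must lie in [0, 1]")
  chk(num1(cfg$fs) && cfg$fs > 0, "fs", "must be > 0")
  chk(num1(cfg$duration) && cfg$duration > 0, "duration", "must be > 0")
  chk(num1(cfg$notch_fraction) && cfg$notch_fraction > 0 &&
        cfg$notch_fraction < 1, "notch_fraction", "must lie in (0, 1)")
  chk(num1(cfg$dia_fraction) && cfg$dia_fraction > 0 && cfg$dia_fraction < 1,
      "dia_fraction", "must lie in (0, 1)")
  chk(num1(cfg$pat_ptt_gap) && cfg$pat_ptt_gap > 0, "pat_ptt_gap",
      "must be > 0")
  chk(num1(cfg$ptt_sptt_gap) && cfg$ptt_sptt_gap > 0, "ptt_sptt_gap",
      "must be > 0")
  chk(num1(cfg$height_sd) && cfg$height_sd > 0, "height_sd", "must be > 0")
  chk(num1(cfg$hr_sd) && cfg$hr_sd >= 0, "hr_sd", "must be >= 0")
  chk(num1(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(num1(cfg$wander_amp) && cfg$wander_amp >= 0, "wander_amp",
      "must be >= 0")
  chk(num1(cfg$powerline_amp) && cfg$powerline_amp >= 0, "powerline_amp",
      "must be >= 0")
  chk(num1(cfg$notch_level) && cfg$notch_level > 0.05 && cfg$notch_level < 0.9,
      "notch_level", "must lie in (0.05, 0.9)")
  for (f in c("height_mean_male", "height_mean_female")) {
    chk(num1(cfg[[f]]) && cfg[[f]] > 1.2 && cfg[[f]] < 2.2, f,
        "must lie in (1.2, 2.2) meters")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects (%.0f%% male), seed %d\n",
              x$n_subjects, 100 * x$sex_ratio, as.integer(x$seed)))
  cat(sprintf("  fs %g Hz, duration %g s\n", x$fs, x$duration))
  cat(sprintf("  base PTT finger/toe %g/%g ms; sex effect %g/%g ms\n",
              x$base_ptt_finger, x$base_ptt_toe,
              x$sex_effect_finger, x$sex_effect_toe))
  cat(sprintf("  height slope %g ms/m, HR coupling %g ms/bpm\n",
              x$height_slope, x$hr_ptt_coupling))
  invisible(x)
}

#' Statistical battery configuration
#'
#' @param alpha Significance level for the p-value part of the gate.
#' @param r2_min Minimum coefficient of determination; a comparison is called
#'   significant only when `p < alpha` **and** `r^2 > r2_min` (with the
#'   default 0.11 this is `|r| > 0.33`).
#' @param ttest_variant `"pooled"` (classic Student, equal variances) or
#'   `"welch"`.
#' @param exclude_confounded Drop smokers and hypertensive subjects before
#'   the battery (off by default: they are retained in the reference
#'   analysis, their numbers being too low for a separate stratum).
#'
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, r2_min = 0.11,
                         ttest_variant = c("pooled", "welch"),
                         exclude_confounded = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
            is.numeric(r2_min), length(r2_min) == 1, r2_min >= 0, r2_min < 1)
  cfg <- list(alpha = alpha, r2_min = r2_min,
              ttest_variant = match.arg(ttest_variant),
              exclude_confounded = isTRUE(exclude_confounded))
  class(cfg) <- "stats_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' The file may contain top-level keys `cohort`, `stats`, `qrs`, and
#' `fiducials`, each a flat mapping of the corresponding constructor's
#' arguments; absent keys fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `cohort` (`cohort_config`), `stats`
#'   (`stats_config`), `qrs` (`qrs_options`), `fiducials`
#'   (`fiducial_options`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build <- function(fun, args) {
    if (is.null(args)) args <- list()
    known <- names(formals(fun))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      stop(sprintf("unknown configuration key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(fun, args)
  }
  list(cohort    = build(cohort_config, raw$cohort),
       stats     = build(stats_config, raw$stats),
       qrs       = build(qrs_options, raw$qrs),
       fiducials = build(fiducial_options, raw$fiducials))
}
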