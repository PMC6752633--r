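#' Generate one synthetic subject
#'
#' Draws the metadata record for a single subject: sex (by `sex_ratio`),
#' height from the sex-specific normal, weight through a BMI draw, age,
#' smoker / hypertension flags, and optionally-missing resting blood
#' pressure.  Fully determined by `rng_seed`.
#'
#' @param config A [cohort_config()].
#' @param rng_seed Integer seed for this subject's metadata substream.
#' @param subject_id Label for the subject (default `"S1"`).
#' @return A one-row [tibble::tibble()] with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`), `age`, `height`, `weight`, `smoker`,
#'   `hypertensive`, `sbp`, `dbp` (the last two possibly `NA`).
#' @export
generate_subject <- function(config, rng_seed, subject_id = "S1") {
  validate_cohort_config(config)
  set.seed(as.integer(rng_seed))
  male <- stats::runif(1) < config$sex_ratio
  h_mean <- if (male) config$height_mean_male else config$height_mean_female
  height <- rnorm_trunc(1, h_mean, config$height_sd, 1.21, 2.19)
  bmi <- rnorm_trunc(1, 24, 3.5, 17, 40)
  weight <- pmin(pmax(bmi * height^2, 30.5), 199)
  age <- round(rnorm_trunc(1, 25, 7, 18.1, 89))
  smoker <- stats::runif(1) < 11 / 80
  hypertensive <- stats::runif(1) < 6 / 80
  bp_absent <- stats::runif(1) < config$bp_missing
  sbp <- if (bp_absent) NA_real_ else round(rnorm_trunc(1, config$sbp_mean, config$sbp_sd, 85, 190))
  dbp <- if (bp_absent) NA_real_ else round(rnorm_trunc(1, config$dbp_mean, config$dbp_sd, 45, 120))
  tibble::new_tibble(list(
    subject_id = subject_id,
    sex = if (male) "male" else "female",
    age = age, height = height, weight = weight,
    smoker = smoker, hypertensive = hypertensive,
    sbp = sbp, dbp = dbp
  ), nrow = 1L)
}

# Hard physiologic bounds used by the programmer: RR is kept in [0.5, 2.5] s
# and the onset->systolic span below notch_fraction * RR_min so every beat's
# landmark ordering (onset < rising < systolic < notch < diastolic < end)
# holds by construction.
RR_MIN <- 0.5
RR_MAX <- 2.5
GAP1_BOUNDS <- c(15, 60)    # onset -> rising, ms
GAP2_BOUNDS <- c(30, 100)   # rising -> systolic, ms

# Draw the latent per-subject program: heart rate, beat times, per-site
# latencies and pulse-shape parameters.  Consumes the current RNG stream.
subject_program <- function(subject, config) {
  max_span_ms <- GAP1_BOUNDS[2] + GAP2_BOUNDS[2]
  if (config$notch_fraction * RR_MIN * 1000 <= max_span_ms + 5) {
    stop("invalid cohort configuration: field 'notch_fraction' too small ",
         "for the onset-to-systolic span", call. = FALSE)
  }
  male <- subject$sex == "male"
  hr <- rnorm_trunc(1, config$hr_mean, config$hr_sd, 45, 115)

  rr0 <- 60 / hr
  n_guess <- ceiling((config$duration + 5) / RR_MIN)
  rr <- pmin(pmax(rr0 * exp(stats::rnorm(n_guess, 0, config$rr_jitter_sd)),
                  RR_MIN), RR_MAX)
  r_times <- 0.25 + cumsum(c(0, rr))[seq_len(n_guess)]
  keep <- r_times <= config$duration + 2
  r_times <- r_times[keep]
  rr <- rr[seq_len(length(r_times))]
  if (sum(r_times <= config$duration) < 1) {
    stop("input error: duration too short to contain one beat", call. = FALSE)
  }

  gap1 <- rnorm_trunc(1, config$pat_ptt_gap, config$gap_sd,
                      GAP1_BOUNDS[1], GAP1_BOUNDS[2])
  gap2 <- rnorm_trunc(1, config$ptt_sptt_gap, config$gap_sd,
                      GAP2_BOUNDS[1], GAP2_BOUNDS[2])
  notch_level <- rnorm_trunc(1, config$notch_level, config$notch_level_sd,
                             0.15, 0.70)

  site_par <- function(base, sex_effect, dia_amp_mean, subject_sd) {
    ptt <- base + sex_effect * male +
      config$height_slope * (subject$height - config$height_ref) +
      config$hr_ptt_coupling * (hr - config$hr_mean) +
      stats::rnorm(1, 0, subject_sd)
    ptt <- pmin(pmax(ptt, gap1 + 30), 650)
    list(pat = ptt - gap1, ptt = ptt, sptt = ptt + gap2,
         dia_amp = rnorm_trunc(1, dia_amp_mean, config$dia_amp_sd,
                               0.02, 0.35))
  }
  finger <- site_par(config$base_ptt_finger, config$sex_effect_finger,
                     config$dia_amp_finger, config$ptt_subject_sd_finger)
  toe <- site_par(config$base_ptt_toe, config$sex_effect_toe,
                  config$dia_amp_toe, config$ptt_subject_sd_toe)

  list(hr = hr, r_times = r_times, rr = rr,
       gap1 = gap1, gap2 = gap2, notch_level = notch_level,
       finger = finger, toe = toe)
}

# Landmark times (seconds) for every beat of one site, given the program.
site_landmarks <- function(program, site, config) {
  p <- program[[site]]
  r <- program$r_times
  rr <- program$rr
  onset <- r + p$pat / 1000
  rising <- r + p$ptt / 1000
  systolic <- r + p$sptt / 1000
  endt <- onset + rr
  notch <- onset + config$notch_fraction * rr
  dia <- notch + config$dia_fraction * (endt - notch)
  tibble::new_tibble(list(beat = seq_along(r), r_time = r,
                          onset_time = onset, rising_time = rising,
                          systolic_time = systolic, notch_time = notch,
                          diastolic_time = dia, end_time = endt),
                     nrow = length(r))
}

tag_landmarks <- function(lm, site, subject_id) {
  n <- nrow(lm)
  tibble::new_tibble(c(list(site = rep(site, n),
                            subject_id = rep(subject_id, n)),
                       as.list(lm)), nrow = n)
}

# Evaluate the two-lobe pulse at offsets `u` (seconds past onset).  The
# waveform is C1: five cosine pieces joined with zero slope at the systolic
# peak, notch, diastolic peak and cycle end, and maximum slope exactly at
# the rising point.  Unit systolic amplitude.
ppg_pulse_eval <- function(u, w1, w2, w3, w4, w5, notch_level, dia_amp) {
  h1 <- w1 / (w1 + w2)
  h2 <- w2 / (w1 + w2)
  pd <- notch_level + dia_amp
  b <- cumsum(c(0, w1, w2, w3, w4, w5))
  out <- numeric(length(u))
  piece <- findInterval(u, b, rightmost.closed = TRUE)
  i <- piece == 1L
  out[i] <- h1 * (1 - cos(pi * u[i] / (2 * w1)))
  i <- piece == 2L
  out[i] <- h1 + h2 * sin(pi * (u[i] - b[2]) / (2 * w2))
  i <- piece == 3L
  out[i] <- 1 - (1 - notch_level) / 2 * (1 - cos(pi * (u[i] - b[3]) / w3))
  i <- piece == 4L
  out[i] <- notch_level + dia_amp / 2 * (1 - cos(pi * (u[i] - b[4]) / w4))
  i <- piece == 5L
  out[i] <- pd - pd / 2 * (1 - cos(pi * (u[i] - b[5]) / w5))
  out[u < 0 | u > b[6]] <- 0
  out
}

# Closed-form sub-areas of the unit pulse (signal * seconds, zero baseline):
# S1 onset->rising, S2 rising->systolic, S3 systolic->notch,
# S4 notch->cycle end.
pulse_true_areas <- function(w1, w2, w3, w4, w5, notch_level, dia_amp) {
  h1 <- w1 / (w1 + w2)
  h2 <- w2 / (w1 + w2)
  pd <- notch_level + dia_amp
  s1 <- h1 * w1 * (1 - 2 / pi)
  s2 <- h1 * w2 + h2 * 2 * w2 / pi
  s3 <- w3 * (1 + notch_level) / 2
  s4 <- w4 * (notch_level + dia_amp / 2) + w5 * pd / 2
  c(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}

render_ppg <- function(landmarks, n, fs, notch_level, dia_amp) {
  sig <- numeric(n)
  t0 <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(landmarks))) {
    lm <- landmarks[i, ]
    i0 <- max(1L, ceiling(lm$onset_time * fs) + 1L)
    i1 <- min(n, floor(lm$end_time * fs) + 1L)
    if (i0 > i1) next
    u <- t0[i0:i1] - lm$onset_time
    sig[i0:i1] <- sig[i0:i1] + ppg_pulse_eval(
      u,
      w1 = lm$rising_time - lm$onset_time,
      w2 = lm$systolic_time - lm$rising_time,
      w3 = lm$notch_time - lm$systolic_time,
      w4 = lm$diastolic_time - lm$notch_time,
      w5 = lm$end_time - lm$diastolic_time,
      notch_level = notch_level, dia_amp = dia_amp)
  }
  sig
}

# Narrow biphasic QRS complex: raised-cosine R deflection flanked by small
# negative Q and S lobes.  Only the R landmark matters downstream.
render_ecg <- function(r_times, n, fs) {
  sig <- numeric(n)
  t0 <- (seq_len(n) - 1) / fs
  bump <- function(center, width, amp) {
    i0 <- max(1L, ceiling((center - width / 2) * fs) + 1L)
    i1 <- min(n, floor((center + width / 2) * fs) + 1L)
    if (i0 > i1) return(invisible())
    tt <- t0[i0:i1] - center
    sig[i0:i1] <<- sig[i0:i1] + amp * 0.5 * (1 + cos(2 * pi * tt / width))
    invisible()
  }
  for (r in r_times) {
    bump(r - 0.030, 0.020, -0.10)
    bump(r, 0.024, 1.0)
    bump(r + 0.030, 0.020, -0.15)
  }
  sig
}

add_channel_noise <- function(sig, fs, config) {
  n <- length(sig)
  t0 <- (seq_len(n) - 1) / fs
  out <- sig
  if (config$noise_sd > 0) out <- out + stats::rnorm(n, 0, config$noise_sd)
  if (config$wander_amp > 0) {
    fw <- stats::runif(1, 0.15, 0.35)
    out <- out + config$wander_amp * sin(2 * pi * fw * t0 + stats::runif(1, 0, 2 * pi))
  }
  if (config$powerline_amp > 0) {
    out <- out + config$powerline_amp * sin(2 * pi * 60 * t0 + stats::runif(1, 0, 2 * pi))
  }
  out
}

#' Generate one co-registered ECG + finger/toe PPG recording
#'
#' Renders the subject's programmed waveforms and returns the raw recording
#' together with its full ground-truth annotation.  All landmark times are
#' stored in seconds at full precision; quantization to samples happens only
#' in the rendered waveforms.  Noise (broadband, baseline wander, powerline)
#' is added last, per channel.
#'
#' @param subject One-row subject tibble from [generate_subject()].
#' @param config A [cohort_config()].
#' @param rng_seed Integer seed for this subject's physiology/noise
#'   substream.
#' @return A list with elements
#'   \describe{
#'     \item{recording}{class `raw_recording`: `ecg`, `ppg_finger`,
#'       `ppg_toe` numeric series, `fs`, and the `subject` row.}
#'     \item{truth}{list with `beats` (per-beat, per-site landmark times in
#'       seconds) and `subject` (one row of programmed per-subject values:
#'       true HR and VHR, true PAT/PTT/SPTT/DPTT per site in ms, true IPA
#'       and S2/S1 from the closed-form pulse areas).}
#'   }
#' @export
generate_recording <- function(subject, config, rng_seed) {
  validate_cohort_config(config)
  set.seed(as.integer(rng_seed))
  program <- subject_program(subject, config)
  n <- round(config$fs * config$duration)
  fs <- config$fs

  lm_f <- site_landmarks(program, "finger", config)
  lm_t <- site_landmarks(program, "toe", config)

  ecg <- render_ecg(program$r_times, n, fs)
  ppg_f <- render_ppg(lm_f, n, fs, program$notch_level, program$finger$dia_amp)
  ppg_t <- render_ppg(lm_t, n, fs, program$notch_level, program$toe$dia_amp)

  ecg <- add_channel_noise(ecg, fs, config)
  ppg_f <- add_channel_noise(ppg_f, fs, config)
  ppg_t <- add_channel_noise(ppg_t, fs, config)

  rec <- structure(list(ecg = ecg, ppg_finger = ppg_f, ppg_toe = ppg_t,
                        fs = fs, subject = subject),
                   class = "raw_recording")
  truth <- list(
    beats = rbind(tag_landmarks(lm_f, "finger", subject$subject_id),
                  tag_landmarks(lm_t, "toe", subject$subject_id)),
    subject = subject_truth_row(subject, program, config)
  )
  list(recording = rec, truth = truth)
}

# One row of programmed per-subject ground truth in the cohort-table schema.
subject_truth_row <- function(subject, program, config) {
  in_rec <- program$r_times <= config$duration
  rr_used <- program$rr[in_rec]
  ihr <- 60 / rr_used
  mean_rr <- mean(rr_used)
  site_cols <- function(site) {
    p <- program[[site]]
    rrm <- mean_rr
    dptt <- p$pat + (config$notch_fraction +
                       config$dia_fraction * (1 - config$notch_fraction)) *
      rrm * 1000
    ar <- pulse_true_areas(
      w1 = (p$ptt - p$pat) / 1000, w2 = (p$sptt - p$ptt) / 1000,
      w3 = config$notch_fraction * rrm - (p$sptt - p$pat) / 1000,
      w4 = config$dia_fraction * (1 - config$notch_fraction) * rrm,
      w5 = (1 - config$dia_fraction) * (1 - config$notch_fraction) * rrm,
      notch_level = program$notch_level, dia_amp = p$dia_amp)
    out <- list(
      pat = p$pat, ptt = p$ptt, sptt = p$sptt, dptt = dptt,
      ipa = unname(ar["s4"] / sum(ar[c("s1", "s2", "s3")])),
      s2_over_s1 = unname(ar["s2"] / ar["s1"]),
      pat_norm = p$pat / subject$height,
      ptt_norm = p$ptt / subject$height,
      n_beats = sum(in_rec))
    names(out) <- paste0(names(out), "_", site)
    out
  }
  tibble::new_tibble(c(
    as.list(subject),
    list(bmi = subject$weight / subject$height^2,
         sex_male = as.integer(subject$sex == "male"),
         hr_mean = mean(ihr), vhr = pop_var(ihr)),
    site_cols("finger"), site_cols("toe")
  ), nrow = 1L)
}

#' Generate a seeded synthetic cohort
#'
#' Derives independent per-subject random substreams from the single root
#' seed in `config`, so cohorts are exactly reproducible and subjects are
#' independent.
#'
#' @param config A [cohort_config()].
#' @param render If `FALSE`, skip waveform rendering and return only the
#'   ground-truth tables (fast path for calibration studies; the programmed
#'   values are identical to a rendered run at the same seed).
#' @return A list with `recordings` (list of `raw_recording`, `NULL` when
#'   `render = FALSE`), `subjects` (metadata tibble), `truth_beats`
#'   (per-beat landmark times), and `truth_subjects` (per-subject programmed
#'   values in the cohort-table schema).
#' @export
generate_cohort <- function(config, render = TRUE) {
  validate_cohort_config(config)
  n <- as.integer(config$n_subjects)
  seeds <- derive_seeds(config$seed, 2L * n)
  ids <- sprintf("S%03d", seq_len(n))
  recordings <- if (render) vector("list", n) else NULL
  subjects <- vector("list", n)
  truth_b <- vector("list", n)
  truth_s <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generate_subject(config, seeds[2L * i - 1L], ids[i])
    if (render) {
      gen <- generate_recording(subj, config, seeds[2L * i])
      recordings[[i]] <- gen$recording
      truth_b[[i]] <- gen$truth$beats
      truth_s[[i]] <- gen$truth$subject
    } else {
      set.seed(seeds[2L * i])
      program <- subject_program(subj, config)
      truth_b[[i]] <- rbind(
        tag_landmarks(site_landmarks(program, "finger", config), "finger",
                      subj$subject_id),
        tag_landmarks(site_landmarks(program, "toe", config), "toe",
                      subj$subject_id))
      truth_s[[i]] <- subject_truth_row(subj, program, config)
    }
    subjects[[i]] <- subj
  }
  list(recordings = recordings,
       subjects = do.call(rbind, subjects),
       truth_beats = tibble::as_tibble(do.call(rbind, truth_b)),
       truth_subjects = tibble::as_tibble(do.call(rbind, truth_s)))
}

#' Ground-truth cohort feature table
#'
#' Builds the per-subject feature table directly from the generator's
#' programmed values, without rendering or analysing any waveform.  The
#' result has the same schema as [extract_cohort_features()] and is the fast
#' path for statistical calibration studies (e.g. null false-positive-rate
#' sweeps over many seeded replicates).
#'
#' @param config A [cohort_config()].
#' @return A tibble, one row per subject.
#' @export
cohort_truth_table <- function(config) {
  res <- generate_cohort(config, render = FALSE)
  tab <- res$truth_subjects
  attr(tab, "ppgcohort_schema") <- feature_schema_version()
  tab
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d samples @ %g Hz (%.1f s), channels ecg/ppg_finger/ppg_toe\n",
              x$subject$subject_id, length(x$ecg), x$fs, length(x$ecg) / x$fs))
  invisible(x)
}
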