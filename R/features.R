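#' Per-beat latency features
#'
#' PAT is the delay from the R peak to the PPG onset, PTT to the rising
#' (maximum-slope) point, SPTT to the systolic peak, and DPTT to the
#' diastolic peak (when present).  All in milliseconds.
#'
#' @param fiducials Tibble of beat fiducials (valid beats).
#' @param fs Sampling rate (Hz).
#' @return Tibble with `beat_id`, `pat`, `ptt`, `sptt`, `dptt` (ms; `dptt`
#'   `NA` where no diastolic peak was found).
#' @export
compute_latencies <- function(fiducials, fs) {
  if (any(!fiducials$valid)) {
    bad <- fiducials$beat_id[!fiducials$valid]
    stop(sprintf("input error: invalid beat(s) %s passed to compute_latencies",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  ms <- function(idx) (idx - fiducials$r_index) / fs * 1000
  tibble::tibble(beat_id = fiducials$beat_id,
                 pat = ms(fiducials$onset_index),
                 ptt = ms(fiducials$rising_index),
                 sptt = ms(fiducials$systolic_index),
                 dptt = ms(fiducials$diastolic_index))
}

#' Per-beat waveform area morphology
#'
#' Trapezoidal integrals of the signal above the beat's baseline (the
#' amplitude at the onset sample) over the landmark-delimited intervals:
#' S1 onset to rising point, S2 rising point to systolic peak, S3 systolic
#' peak to dicrotic notch, S4 notch to cycle end.  A1 = S1+S2+S3,
#' A2 = S4, IPA = A2/A1, plus the S2/S1 ratio.  Beats whose S1 or A1 is
#' non-positive are invalidated (division guard), not errored.
#'
#' @param ppg Filtered PPG series (the full channel).
#' @param fiducials Tibble of valid beat fiducials with notch present.
#' @param fs Sampling rate (Hz).
#' @return Tibble with `beat_id`, `s1`..`s4`, `a1`, `a2`, `ipa`,
#'   `s2_over_s1`, `area_valid`.
#' @export
compute_areas <- function(ppg, fiducials, fs) {
  dt <- 1 / fs
  nb <- nrow(fiducials)
  s1 <- s2 <- s3 <- s4 <- rep(NA_real_, nb)
  area_valid <- rep(FALSE, nb)
  for (i in seq_len(nb)) {
    if (!isTRUE(fiducials$valid[i]) || is.na(fiducials$notch_index[i])) next
    base <- ppg[fiducials$onset_index[i]]
    seg_area <- function(i0, i1) {
      if (i1 <= i0) return(0)
      y <- ppg[i0:i1] - base
      pracma::trapz(seq(0, by = dt, length.out = i1 - i0 + 1L), y)
    }
    s1[i] <- seg_area(fiducials$onset_index[i], fiducials$rising_index[i])
    s2[i] <- seg_area(fiducials$rising_index[i], fiducials$systolic_index[i])
    s3[i] <- seg_area(fiducials$systolic_index[i], fiducials$notch_index[i])
    s4[i] <- seg_area(fiducials$notch_index[i], fiducials$end_index[i])
    area_valid[i] <- is.finite(s1[i]) && s1[i] > 0 &&
      is.finite(s1[i] + s2[i] + s3[i]) && (s1[i] + s2[i] + s3[i]) > 0
  }
  a1 <- s1 + s2 + s3
  tibble::tibble(beat_id = fiducials$beat_id, s1 = s1, s2 = s2, s3 = s3,
                 s4 = s4, a1 = a1, a2 = s4,
                 ipa = ifelse(area_valid, s4 / a1, NA_real_),
                 s2_over_s1 = ifelse(area_valid, s2 / s1, NA_real_),
                 area_valid = area_valid)
}

#' Combined per-beat feature table for one site
#'
#' @param ppg Filtered PPG series.
#' @param fiducials Valid beat fiducials (after [apply_quality_policy()]).
#' @param fs Sampling rate (Hz).
#' @return Tibble joining latencies and areas by beat.
#' @export
beat_features <- function(ppg, fiducials, fs) {
  lat <- compute_latencies(fiducials, fs)
  ar <- compute_areas(ppg, fiducials, fs)
  cbind(lat, ar[match(lat$beat_id, ar$beat_id), -1, drop = FALSE])
}

feature_schema_version <- function() "ppgcohort/features/v1"

# Zero-row marker for an excluded subject; the reason travels in the
# "exclusion" attribute.
subject_exclusion <- function(reason) {
  out <- tibble::tibble()
  attr(out, "exclusion") <- reason
  out
}

is_excluded <- function(x) {
  is.null(x) || (is.data.frame(x) && nrow(x) == 0)
}

#' Aggregate per-beat features into one subject record
#'
#' Site-wise means over valid beats of the latency and morphology features,
#' BMI (`weight / height^2`), height-normalized PAT/PTT (ms per meter of
#' subject height), and the heart-rate summary.
#'
#' @param features_by_site Named list (`finger`, `toe`) of per-beat feature
#'   tibbles from [beat_features()].
#' @param hr Heart-rate feature list from [compute_hr_features()].
#' @param subject One-row subject tibble.
#' @param min_beats Minimum valid beats required per site; below it the
#'   subject is excluded (returns `NULL` with an attribute naming the
#'   reason).
#' @param agg Aggregation statistic, `"mean"` (default) or `"median"`.
#' @return One-row tibble in the cohort feature schema, or `NULL` when the
#'   subject fails the minimum-beats gate.
#' @export
aggregate_subject <- function(features_by_site, hr, subject, min_beats = 5,
                              agg = c("mean", "median")) {
  agg <- match.arg(agg)
  stat <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    if (agg == "mean") mean(x) else stats::median(x)
  }
  for (site in names(features_by_site)) {
    n_ok <- sum(is.finite(features_by_site[[site]]$pat))
    if (n_ok < min_beats) {
      return(subject_exclusion(sprintf(
        "subject %s excluded: %d valid %s beats < minimum %d",
        subject$subject_id, n_ok, site, min_beats)))
    }
  }
  site_cols <- function(site) {
    fb <- features_by_site[[site]]
    out <- list(
      pat = stat(fb$pat), ptt = stat(fb$ptt), sptt = stat(fb$sptt),
      dptt = stat(fb$dptt), ipa = stat(fb$ipa),
      s2_over_s1 = stat(fb$s2_over_s1),
      pat_norm = stat(fb$pat) / subject$height,
      ptt_norm = stat(fb$ptt) / subject$height,
      n_beats = sum(is.finite(fb$pat)))
    names(out) <- paste0(names(out), "_", site)
    out
  }
  tibble::new_tibble(c(
    as.list(subject),
    list(bmi = subject$weight / subject$height^2,
         sex_male = as.integer(subject$sex == "male"),
         hr_mean = hr$hr_mean, vhr = hr$hr_variance),
    unlist(lapply(names(features_by_site), site_cols), recursive = FALSE)
  ), nrow = 1L)
}
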