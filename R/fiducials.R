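#' Fiducial extraction options
#'
#' @param rr_bounds Physiological RR gate (seconds); beats whose window
#'   duration falls outside are invalidated.
#' @param notch_mode `"signal"` locates the dicrotic notch as the most
#'   prominent local minimum of the signal after the systolic peak;
#'   `"second_derivative"` uses the largest positive second-derivative
#'   local maximum in the same range.
#' @param diastolic_mask_threshold Minimum per-site diastolic detection
#'   rate; below it [apply_quality_policy()] masks diastolic-derived
#'   features site-wide.
#' @return An object of class `fiducial_options`.
#' @export
fiducial_options <- function(rr_bounds = c(0.25, 3.0),
                             notch_mode = c("signal", "second_derivative"),
                             diastolic_mask_threshold = 0.5) {
  stopifnot(length(rr_bounds) == 2, rr_bounds[1] > 0,
            rr_bounds[2] > rr_bounds[1],
            diastolic_mask_threshold >= 0, diastolic_mask_threshold <= 1)
  structure(list(rr_bounds = rr_bounds,
                 notch_mode = match.arg(notch_mode),
                 diastolic_mask_threshold = diastolic_mask_threshold),
            class = "fiducial_options")
}

#' Segment a PPG channel into ECG-anchored cardiac cycles
#'
#' One half-open window per R peak except the last: window `i` spans
#' `[r_indices[i], r_indices[i+1])`.
#'
#' @param ppg Filtered PPG series.
#' @param peaks An `r_peak_series` with at least 2 peaks.
#' @return List of beat windows; each is a list with `beat_id`, `signal`
#'   (the in-window samples), `start`/`end` (global 1-based sample indices,
#'   inclusive), and `r_index`.
#' @export
segment_beats <- function(ppg, peaks) {
  stopifnot(is.numeric(ppg), inherits(peaks, "r_peak_series"))
  r <- peaks$r_indices
  if (length(r) < 2) stop("input error: need at least 2 R peaks",
                          call. = FALSE)
  lapply(seq_len(length(r) - 1L), function(i) {
    s <- r[i]
    e <- min(r[i + 1L] - 1L, length(ppg))
    list(beat_id = i, signal = ppg[s:e], start = s, end = e, r_index = s)
  })
}

#' Locate the per-beat PPG landmarks in one cardiac-cycle window
#'
#' Rising point: global maximum of the first difference within the window.
#' Onset: last crossing of the first difference from <= 0 to > 0 at or
#' before the rising point (fallback: the pre-rising signal minimum).
#' Systolic peak: global signal maximum from the rising point onward.
#' Dicrotic notch: most prominent local minimum after the systolic peak.
#' Diastolic peak: largest local maximum after the notch.  Failures and
#' ordering violations are encoded in `valid`/`reject_reason`, never
#' raised; a missing diastolic peak alone leaves the beat valid (its
#' diastolic-derived features are simply absent), so that site-level
#' diastolic detection rates can drive the quality policy.
#'
#' @param window One beat window from [segment_beats()].
#' @param fs Sampling rate (Hz).
#' @param options A [fiducial_options()].
#' @return One-row tibble: `beat_id`, `r_index`, `onset_index`,
#'   `rising_index`, `systolic_index`, `notch_index`, `diastolic_index`,
#'   `end_index` (global 1-based sample indices, `NA` where not found),
#'   `valid`, `reject_reason`.
#' @export
extract_fiducials <- function(window, fs, options = fiducial_options()) {
  tibble::as_tibble(fiducial_scan(window, fs, options))
}

# List-returning core of extract_fiducials (kept off the tibble constructor
# so per-beat scanning stays cheap inside cohort loops).
fiducial_scan <- function(window, fs, options) {
  out <- list(
    beat_id = window$beat_id, r_index = window$r_index,
    onset_index = NA_integer_, rising_index = NA_integer_,
    systolic_index = NA_integer_, notch_index = NA_integer_,
    diastolic_index = NA_integer_, end_index = window$end,
    valid = FALSE, reject_reason = NA_character_)
  reject <- function(reason) { out$reject_reason <- reason; out }

  x <- window$signal
  m <- length(x)
  if (m < 8) return(reject("too_short"))
  rr_s <- m / fs
  if (rr_s <= options$rr_bounds[1] || rr_s >= options$rr_bounds[2]) {
    return(reject("rr_out_of_range"))
  }
  d <- diff(x)
  rise <- which.max(d)
  if (!is.finite(d[rise]) || d[rise] <= 0) return(reject("no_upstroke"))

  # onset: last <=0 -> >0 crossing of the first difference at/before rise
  # (a window that opens already rising counts as a crossing at sample 1)
  dprev <- c(-Inf, d[seq_len(rise - 1L)])
  cand <- which(d[seq_len(rise)] > 0 & dprev <= 0)
  onset <- if (length(cand)) max(cand) else which.min(x[seq_len(rise)])

  sys <- rise - 1L + which.max(x[rise:m])
  out$onset_index <- window$start + onset - 1L
  out$rising_index <- window$start + rise - 1L
  out$systolic_index <- window$start + sys - 1L

  if (!(onset <= rise && rise <= sys && sys < m)) {
    return(reject("landmark_order"))
  }
  if (onset <= 1L) return(reject("onset_at_window_start"))

  notch <- find_notch(x, sys, options$notch_mode)
  if (is.na(notch)) return(reject("notch_not_found"))
  out$notch_index <- window$start + notch - 1L

  # diastolic peak: largest local maximum after the notch (optional)
  if (notch + 2L <= m - 1L) {
    seg <- x[notch:m]
    dd <- diff(seg)
    mx <- which(dd[-length(dd)] > 0 & dd[-1] <= 0) + 1L
    mx <- mx[seg[mx] > seg[1]]
    if (length(mx)) {
      dia <- notch - 1L + mx[which.max(seg[mx])]
      if (dia > notch && dia < m) out$diastolic_index <- window$start + dia - 1L
    }
  }
  out$valid <- TRUE
  out
}

# Most prominent local minimum of x strictly between sys and the window end.
find_notch <- function(x, sys, mode) {
  m <- length(x)
  if (sys + 2L > m - 1L) return(NA_integer_)
  seg <- x[sys:m]
  d <- diff(seg)
  if (mode == "second_derivative") {
    d2 <- diff(d)
    k <- which(d2[-length(d2)] > 0 & d2[-1] <= 0) + 2L
    k <- k[k > 2L & k < length(seg)]
    if (!length(k)) return(NA_integer_)
    return(sys - 1L + k[which.max(d2[k - 1L])])
  }
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  mins <- mins[mins > 1L & mins < length(seg)]
  if (!length(mins)) return(NA_integer_)
  prom <- vapply(mins, function(k) {
    left <- max(seg[seq_len(k - 1L)])
    right <- max(seg[seq((k + 1L), length(seg))])
    min(left, right) - seg[k]
  }, numeric(1))
  mins <- mins[prom > 0]
  prom <- prom[prom > 0]
  if (!length(mins)) return(NA_integer_)
  sys - 1L + mins[which.max(prom)]
}

#' Extract fiducials for every beat of a channel
#'
#' @param ppg Filtered PPG series.
#' @param peaks An `r_peak_series`.
#' @param fs Sampling rate (Hz).
#' @param options A [fiducial_options()].
#' @return Tibble with one row per beat (see [extract_fiducials()]).
#' @export
extract_beat_fiducials <- function(ppg, peaks, fs,
                                   options = fiducial_options()) {
  windows <- segment_beats(ppg, peaks)
  scans <- lapply(windows, fiducial_scan, fs = fs, options = options)
  cols <- names(scans[[1]])
  out <- lapply(cols, function(cl) {
    unlist(lapply(scans, `[[`, cl), use.names = FALSE)
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' Apply the per-site beat quality policy
#'
#' Drops invalid beats and computes the site's diastolic detection rate
#' over the surviving beats.  When that rate falls below
#' `options$diastolic_mask_threshold`, diastolic-derived features (DPTT)
#' are masked site-wide: all `diastolic_index` entries are set `NA` and the
#' report flags the mask, mirroring the practice of removing a site's
#' diastolic features when their detection is unreliable.
#'
#' @param beats Tibble of beat fiducials.
#' @param site Site label (e.g. `"finger"`, `"toe"`).
#' @param options A [fiducial_options()].
#' @return List with `beats` (valid beats, possibly diastolic-masked) and
#'   `report` (site, counts, rejection tally, diastolic rate, mask flag).
#' @export
apply_quality_policy <- function(beats, site, options = fiducial_options()) {
  if (is.null(beats) || nrow(beats) == 0) {
    return(list(beats = beats,
                report = list(site = site, n_total = 0L, n_valid = 0L,
                              rejections = table(character(0)),
                              diastolic_rate = NA_real_,
                              diastolic_masked = FALSE)))
  }
  valid <- beats[beats$valid, , drop = FALSE]
  rate <- if (nrow(valid)) mean(!is.na(valid$diastolic_index)) else NA_real_
  masked <- isTRUE(rate < options$diastolic_mask_threshold)
  if (masked) valid$diastolic_index <- NA_integer_
  list(beats = valid,
       report = list(site = site, n_total = nrow(beats),
                     n_valid = nrow(valid),
                     rejections = table(beats$reject_reason[!beats$valid]),
                     diastolic_rate = rate, diastolic_masked = masked))
}
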