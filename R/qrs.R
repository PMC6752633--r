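#' Five-tap derivative filter for QRS enhancement
#'
#' Computes `V[n] = (2 u[n] + u[n-1] - u[n-3] - 2 u[n-4]) / 8`.  Samples
#' before the start of the series are taken equal to the first sample, so a
#' constant input maps to zero everywhere.
#'
#' @param u Numeric series, length >= 5.
#' @return Filtered series, same length as `u`.
#' @export
derivative_filter <- function(u) {
  n <- length(u)
  if (n < 5) stop("input error: series must have at least 5 samples",
                  call. = FALSE)
  lag <- function(k) c(rep(u[1], k), u[seq_len(n - k)])
  (2 * u + lag(1L) - lag(3L) - 2 * lag(4L)) / 8
}

#' QRS detector options
#'
#' @param threshold_fraction Threshold as a fraction of the running
#'   supra-threshold peak-level estimate.
#' @param smoothing Exponential smoothing factor for the peak-level
#'   estimate, applied at each accepted detection.
#' @param init_window_s Seconds of the integrated signal used to initialize
#'   the peak-level estimate (98th percentile).
#' @param refractory_s Supra-threshold regions beginning within this period
#'   of the previous detection are merged with it.
#' @param annotation `"midpoint"` (midpoint index of the contiguous
#'   supra-threshold region) or `"centroid"` (area centroid of the region
#'   above the threshold).
#' @param ma_ms Moving-average window in milliseconds (32 samples at 1 kHz).
#' @return An object of class `qrs_options`.
#' @export
qrs_options <- function(threshold_fraction = 0.3, smoothing = 0.125,
                        init_window_s = 2, refractory_s = 0.25,
                        annotation = c("midpoint", "centroid"),
                        ma_ms = 32) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            smoothing > 0, smoothing <= 1, refractory_s >= 0, ma_ms > 0)
  structure(list(threshold_fraction = threshold_fraction,
                 smoothing = smoothing, init_window_s = init_window_s,
                 refractory_s = refractory_s,
                 annotation = match.arg(annotation), ma_ms = ma_ms),
            class = "qrs_options")
}

#' Detect ECG R peaks
#'
#' Pipeline: [derivative_filter()], squaring, a causal moving average
#' (32 ms worth of samples), then an adaptive threshold (a fraction of an
#' exponentially smoothed estimate of recent supra-threshold peak levels,
#' initialized from the 98th percentile of the first seconds of the
#' integrated signal).  Each contiguous supra-threshold region is annotated
#' at its temporal midpoint (or area centroid), corrected for the known
#' group delay of the causal filtering chain; regions starting within the
#' refractory period of the previous detection are merged with it.
#'
#' @param ecg Band-limited ECG series.
#' @param fs Sampling rate (Hz).
#' @param options A [qrs_options()].
#' @return An object of class `r_peak_series`: list with `r_indices`
#'   (1-based sample indices, strictly increasing), `fs`, and
#'   `rr_intervals` (seconds, length `length(r_indices) - 1`).  Empty (with
#'   a warning) when nothing crosses the threshold.
#' @export
detect_r_peaks <- function(ecg, fs, options = qrs_options()) {
  stopifnot(is.numeric(ecg), fs > 0)
  n <- length(ecg)
  ma_len <- max(1L, round(options$ma_ms / 1000 * fs))
  v <- derivative_filter(ecg)
  y <- moving_average(v^2, ma_len)
  # Group delay of the causal chain: the derivative filter is antisymmetric
  # about lag 2, the L-sample moving average adds (L-1)/2.
  delay <- round(2 + (ma_len - 1) / 2)

  init_n <- min(n, max(ma_len * 2L, round(options$init_window_s * fs)))
  level <- stats::quantile(y[seq_len(init_n)], 0.98, names = FALSE)
  if (!is.finite(level) || level <= 0) {
    warning("no supra-threshold region found; returning empty result")
    return(new_r_peak_series(integer(0), fs))
  }
  thr <- options$threshold_fraction * level
  refractory <- round(options$refractory_s * fs)

  regions <- list()
  pos <- 1L
  block <- max(1024L, as.integer(2 * fs))
  while (pos <= n) {
    hi <- min(n, pos + block - 1L)
    above <- which(y[pos:hi] > thr)
    if (!length(above)) { pos <- hi + 1L; next }
    start <- pos + above[1] - 1L
    # walk to the end of the contiguous supra-threshold region
    end <- start
    repeat {
      hi2 <- min(n, end + block - 1L)
      below <- which(y[(end + 1L):hi2] <= thr)
      if (length(below)) { end <- end + below[1] - 1L; break }
      end <- hi2
      if (end >= n) break
    }
    k <- length(regions)
    if (k > 0 && (start - regions[[k]]$end) <= refractory) {
      regions[[k]]$end <- end
      regions[[k]]$peak <- max(regions[[k]]$peak, max(y[start:end]))
    } else {
      regions[[k + 1L]] <- list(start = start, end = end,
                                peak = max(y[start:end]))
      level <- level + options$smoothing * (max(y[start:end]) - level)
      thr <- options$threshold_fraction * level
    }
    pos <- end + 1L
  }
  if (!length(regions)) {
    warning("no supra-threshold region found; returning empty result")
    return(new_r_peak_series(integer(0), fs))
  }
  r_idx <- vapply(regions, function(rg) {
    if (options$annotation == "midpoint") {
      as.integer(floor((rg$start + rg$end) / 2))
    } else {
      w <- y[rg$start:rg$end] - thr
      as.integer(round(sum(seq(rg$start, rg$end) * w) / sum(w)))
    }
  }, integer(1)) - delay
  r_idx <- pmax(r_idx, 1L)
  # physiological gating: drop peaks creating RR below the plausible floor
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) / fs > 0.25)
    while (!all(keep)) {
      r_idx <- r_idx[keep]
      keep <- c(TRUE, diff(r_idx) / fs > 0.25)
    }
  }
  new_r_peak_series(r_idx, fs)
}

new_r_peak_series <- function(r_indices, fs) {
  structure(list(r_indices = as.integer(r_indices), fs = fs,
                 rr_intervals = if (length(r_indices) > 1)
                   diff(r_indices) / fs else numeric(0)),
            class = "r_peak_series")
}

#' @export
print.r_peak_series <- function(x, ...) {
  cat(sprintf("<r_peak_series> %d peaks @ %g Hz", length(x$r_indices), x$fs))
  if (length(x$rr_intervals)) {
    cat(sprintf(", median RR %.3f s", stats::median(x$rr_intervals)))
  }
  cat("\n")
  invisible(x)
}

#' Heart-rate features from an R-peak series
#'
#' Instantaneous heart rate is 60 divided by each beat-to-beat RR interval;
#' the summary features are its mean (HR) and population variance (VHR).
#' RR intervals outside the physiological band (0.25, 3.0) s are excluded
#' from the instantaneous series.
#'
#' @param peaks An `r_peak_series` with at least 2 peaks.
#' @return List with `hr_mean` (bpm), `hr_variance` (bpm^2), and
#'   `instantaneous_hr` (bpm per retained RR interval).
#' @export
compute_hr_features <- function(peaks) {
  stopifnot(inherits(peaks, "r_peak_series"))
  if (length(peaks$r_indices) < 2) {
    stop("input error: need at least 2 R peaks", call. = FALSE)
  }
  rr <- peaks$rr_intervals
  rr <- rr[rr > 0.25 & rr < 3.0]
  ihr <- 60 / rr
  list(hr_mean = mean(ihr), hr_variance = pop_var(ihr),
       instantaneous_hr = ihr)
}

#' Export detected R peaks as CSV
#'
#' @param peaks An `r_peak_series`.
#' @param path Output file; columns `index` (1-based sample) and `time_s`.
#' @return `path`, invisibly.
#' @export
write_r_peaks_csv <- function(peaks, path) {
  stopifnot(inherits(peaks, "r_peak_series"))
  readr::write_csv(tibble::tibble(index = peaks$r_indices,
                                  time_s = (peaks$r_indices - 1) / peaks$fs),
                   path)
  invisible(path)
}
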