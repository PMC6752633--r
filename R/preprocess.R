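#' Channel band-limiting filter specification
#'
#' @param highpass_order,highpass_cutoff High-pass Butterworth order and
#'   corner frequency (Hz).
#' @param lowpass_order,lowpass_cutoff Low-pass Butterworth order and corner
#'   frequency (Hz).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_order, highpass_cutoff,
                        lowpass_order, lowpass_cutoff) {
  stopifnot(highpass_order >= 1, lowpass_order >= 1,
            highpass_cutoff > 0, lowpass_cutoff > highpass_cutoff)
  structure(list(highpass_order = as.integer(highpass_order),
                 highpass_cutoff = highpass_cutoff,
                 lowpass_order = as.integer(lowpass_order),
                 lowpass_cutoff = lowpass_cutoff),
            class = "filter_spec")
}

#' Default channel filter specifications
#'
#' PPG channels: 2nd-order high-pass at 0.5 Hz with a 6th-order low-pass at
#' 25 Hz.  ECG channel: 2nd-order high-pass at 0.5 Hz with a 6th-order
#' low-pass at 100 Hz.
#'
#' @return A list with elements `ppg` and `ecg`, each a [filter_spec()].
#' @export
default_filter_specs <- function() {
  list(ppg = filter_spec(2, 0.5, 6, 25),
       ecg = filter_spec(2, 0.5, 6, 100))
}

#' Zero-phase Butterworth band-limiting of one channel
#'
#' Designs the high-pass and low-pass Butterworth stages of `spec` and
#' applies each forward and backward (zero-phase), so fiducial timing is not
#' shifted; the effective attenuation is the squared magnitude response.
#' Edge transients are controlled by odd-reflection padding at both ends,
#' sized to roughly three times the slowest stage's effective
#' impulse-response span.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
filter_channel <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"), is.numeric(x), fs > 0)
  if (spec$lowpass_cutoff >= fs / 2) {
    stop(sprintf(
      "configuration error: lowpass_cutoff (%g Hz) must be below Nyquist (%g Hz)",
      spec$lowpass_cutoff, fs / 2), call. = FALSE)
  }
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * ceiling(fs / spec$highpass_cutoff)))
  if (n < 12L || pad < 9L) {
    stop("input error: series too short to filter", call. = FALSE)
  }
  hp <- signal::butter(spec$highpass_order, spec$highpass_cutoff / (fs / 2),
                       type = "high")
  lp <- signal::butter(spec$lowpass_order, spec$lowpass_cutoff / (fs / 2),
                       type = "low")
  y <- filtfilt_reflect(hp, x, pad)
  filtfilt_reflect(lp, y, pad)
}

# Forward-backward IIR filtering with odd reflection about the endpoints
# (2*x[1] - x[k] style), which pins the extension to the signal's edge
# values and suppresses start-up transients.
filtfilt_reflect <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(head_ext, x, tail_ext)
  y <- signal::filter(filt, ext)
  y <- rev(signal::filter(filt, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Squared magnitude response of a filter specification
#'
#' The zero-phase (forward-backward) gain of [filter_channel()] at
#' frequency `f`, i.e. `|H_hp(f)|^2 * |H_lp(f)|^2`.  Useful as an analytic
#' oracle for attenuation checks.
#'
#' @param spec A [filter_spec()].
#' @param f Frequencies (Hz).
#' @param fs Sampling rate (Hz).
#' @return Numeric gains, same length as `f`.
#' @export
filter_gain <- function(spec, f, fs) {
  hp <- signal::butter(spec$highpass_order, spec$highpass_cutoff / (fs / 2),
                       type = "high")
  lp <- signal::butter(spec$lowpass_order, spec$lowpass_cutoff / (fs / 2),
                       type = "low")
  w <- 2 * pi * f / fs
  mag <- function(ba) {
    num <- vapply(w, function(wi)
      abs(sum(ba$b * exp(-1i * wi * (seq_along(ba$b) - 1)))), numeric(1))
    den <- vapply(w, function(wi)
      abs(sum(ba$a * exp(-1i * wi * (seq_along(ba$a) - 1)))), numeric(1))
    num / den
  }
  (mag(hp) * mag(lp))^2
}

#' Filter all channels of a raw recording
#'
#' Applies the ECG spec to the ECG channel and the PPG spec to both PPG
#' channels.
#'
#' @param rec A `raw_recording`.
#' @param specs List with `ppg` and `ecg` [filter_spec()]s
#'   (default [default_filter_specs()]).
#' @return A `raw_recording` with filtered channels.
#' @export
preprocess_recording <- function(rec, specs = default_filter_specs()) {
  stopifnot(inherits(rec, "raw_recording"))
  out <- rec
  out$ecg <- filter_channel(rec$ecg, rec$fs, specs$ecg)
  out$ppg_finger <- filter_channel(rec$ppg_finger, rec$fs, specs$ppg)
  out$ppg_toe <- filter_channel(rec$ppg_toe, rec$fs, specs$ppg)
  out
}
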