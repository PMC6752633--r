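#' Run the full per-recording pipeline
#'
#' Filters all channels, detects R peaks, extracts per-beat PPG fiducials
#' for both sites, applies the beat quality policy, computes latency and
#' area features, and aggregates them into one subject record.
#'
#' @param rec A `raw_recording`.
#' @param specs Channel filter specs ([default_filter_specs()]).
#' @param qrs_opts A [qrs_options()].
#' @param fid_opts A [fiducial_options()].
#' @param min_beats Minimum valid beats per site for inclusion.
#' @return List with `record` (one-row feature tibble or `NULL` if the
#'   subject was excluded), `peaks`, `fiducials` (per-site tibbles),
#'   `beat_features` (per-site tibbles), and `log` (per-stage counts and
#'   quality reports).
#' @export
process_recording <- function(rec, specs = default_filter_specs(),
                              qrs_opts = qrs_options(),
                              fid_opts = fiducial_options(),
                              min_beats = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  filt <- preprocess_recording(rec, specs)
  peaks <- detect_r_peaks(filt$ecg, filt$fs, qrs_opts)
  if (length(peaks$r_indices) < 3) {
    out <- subject_exclusion(sprintf(
      "subject %s excluded: only %d R peaks detected",
      rec$subject$subject_id, length(peaks$r_indices)))
    return(list(record = out, peaks = peaks, fiducials = NULL,
                beat_features = NULL,
                log = list(exclusion = attr(out, "exclusion"))))
  }
  hr <- compute_hr_features(peaks)

  site_run <- function(ppg, site) {
    fids <- extract_beat_fiducials(ppg, peaks, filt$fs, fid_opts)
    qp <- apply_quality_policy(fids, site, fid_opts)
    feats <- if (nrow(qp$beats)) beat_features(ppg, qp$beats, filt$fs) else
      beat_features(ppg, fids[0, ], filt$fs)
    list(fiducials = qp$beats, features = feats, report = qp$report)
  }
  fin <- site_run(filt$ppg_finger, "finger")
  toe <- site_run(filt$ppg_toe, "toe")

  record <- aggregate_subject(
    list(finger = fin$features, toe = toe$features), hr, rec$subject,
    min_beats = min_beats)
  list(record = record,
       peaks = peaks,
       fiducials = list(finger = fin$fiducials, toe = toe$fiducials),
       beat_features = list(finger = fin$features, toe = toe$features),
       log = list(n_peaks = length(peaks$r_indices),
                  finger = fin$report, toe = toe$report,
                  exclusion = attr(record, "exclusion")))
}

#' Extract the cohort feature table from a set of recordings
#'
#' @param recordings List of `raw_recording` objects.
#' @param specs,qrs_opts,fid_opts,min_beats Passed to
#'   [process_recording()].
#' @return A tibble with one row per retained subject (attribute
#'   `ppgcohort_schema` records the schema version); excluded subjects are
#'   listed in the `exclusions` attribute.
#' @export
extract_cohort_features <- function(recordings,
                                    specs = default_filter_specs(),
                                    qrs_opts = qrs_options(),
                                    fid_opts = fiducial_options(),
                                    min_beats = 5) {
  rows <- list()
  exclusions <- character(0)
  for (rec in recordings) {
    res <- process_recording(rec, specs, qrs_opts, fid_opts, min_beats)
    if (is_excluded(res$record)) {
      exclusions <- c(exclusions, res$log$exclusion)
    } else {
      rows[[length(rows) + 1L]] <- res$record
    }
  }
  tab <- if (length(rows)) tibble::as_tibble(do.call(rbind, rows)) else
    tibble::tibble()
  attr(tab, "ppgcohort_schema") <- feature_schema_version()
  attr(tab, "exclusions") <- exclusions
  tab
}
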