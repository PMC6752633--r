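#' Write a recording to CSV
#'
#' Four columns: `time_s`, `ecg`, `ppg_finger`, `ppg_toe`.
#'
#' @param rec A `raw_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  n <- length(rec$ecg)
  readr::write_csv(tibble::tibble(
    time_s = (seq_len(n) - 1) / rec$fs,
    ecg = rec$ecg, ppg_finger = rec$ppg_finger, ppg_toe = rec$ppg_toe),
    path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path CSV with columns `time_s`, `ecg`, `ppg_finger`, `ppg_toe`.
#' @param subject Optional one-row subject tibble to attach.
#' @return A `raw_recording` (fs inferred from the time column).
#' @export
read_recording_csv <- function(path, subject = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "ecg", "ppg_finger", "ppg_toe")
  if (!all(need %in% names(df))) {
    stop(sprintf("input error: %s lacks required columns (%s)", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(ecg = df$ecg, ppg_finger = df$ppg_finger,
                 ppg_toe = df$ppg_toe, fs = round(fs, 6),
                 subject = subject),
            class = "raw_recording")
}

#' Write / read the cohort feature table
#'
#' The CSV carries its schema version on a leading comment line so that
#' downstream analysis can refuse tables it does not recognize.
#'
#' @param tab Feature table (from [extract_cohort_features()] or
#'   [cohort_truth_table()]).
#' @param path File path.
#' @return `path` ([write_feature_table()]) or the tibble with the schema
#'   attribute restored ([read_feature_table()]).
#' @export
write_feature_table <- function(tab, path) {
  schema <- attr(tab, "ppgcohort_schema")
  if (is.null(schema)) schema <- feature_schema_version()
  writeLines(sprintf("# schema: %s", schema), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1)
  schema <- sub("^# schema: ", "", first)
  if (!startsWith(first, "# schema: ")) {
    stop(sprintf("input error: %s has no schema header", path),
         call. = FALSE)
  }
  if (!identical(schema, feature_schema_version())) {
    stop(sprintf(
      "unrecognized feature-table schema '%s' (expected '%s'); re-extract the table with this package version",
      schema, feature_schema_version()), call. = FALSE)
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(tab, "ppgcohort_schema") <- schema
  tab
}

write_manifest <- function(dir, config, extra = list()) {
  cfg <- unclass(config)
  manifest <- c(list(
    package = "ppgcohort",
    version = as.character(utils::packageVersion("ppgcohort")),
    seed = as.integer(config$seed),
    config_hash = rlang::hash(cfg),
    config = cfg,
    created = "see config_hash; outputs are deterministic in seed+config"),
    extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort to disk
#'
#' Writes one recording CSV per subject, the subject metadata table, the
#' per-beat and per-subject ground-truth tables, and a manifest (seed,
#' config hash, package version) sufficient to reproduce the outputs
#' bit-identically.
#'
#' @param config A [cohort_config()], or the path to a YAML run
#'   configuration (its `cohort` block is used).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of written file paths.
#' @export
cmd_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)$cohort
  validate_cohort_config(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("I/O error: cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  res <- generate_cohort(config)
  paths <- character(0)
  for (rec in res$recordings) {
    p <- file.path(out_dir, paste0(rec$subject$subject_id, ".csv"))
    write_recording_csv(rec, p)
    paths <- c(paths, p)
  }
  p_meta <- file.path(out_dir, "subjects.csv")
  readr::write_csv(res$subjects, p_meta)
  p_tb <- file.path(out_dir, "truth_beats.csv")
  readr::write_csv(res$truth_beats, p_tb)
  p_ts <- file.path(out_dir, "truth_subjects.csv")
  readr::write_csv(res$truth_subjects, p_ts)
  write_manifest(out_dir, config,
                 list(n_recordings = length(res$recordings)))
  invisible(c(paths, p_meta, p_tb, p_ts,
              file.path(out_dir, "manifest.json")))
}

#' Extract the cohort feature table from simulated recordings on disk
#'
#' Reads every per-subject recording CSV in `dir` (as written by
#' [cmd_simulate()], with `subjects.csv` alongside), runs the full
#' pipeline, and writes the feature table plus an extraction log.
#' Malformed recording files are reported and skipped; the run continues.
#'
#' @param dir Directory of recordings.
#' @param out_path Output CSV for the feature table.
#' @param specs,qrs_opts,fid_opts,min_beats Pipeline options.
#' @return The feature table, invisibly.
#' @export
cmd_extract <- function(dir, out_path = file.path(dir, "features.csv"),
                        specs = default_filter_specs(),
                        qrs_opts = qrs_options(),
                        fid_opts = fiducial_options(),
                        min_beats = 5) {
  meta_path <- file.path(dir, "subjects.csv")
  if (!file.exists(meta_path)) {
    stop(sprintf("input error: %s not found", meta_path), call. = FALSE)
  }
  subjects <- readr::read_csv(meta_path, show_col_types = FALSE,
                              progress = FALSE)
  recordings <- list()
  problems <- character(0)
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    p <- file.path(dir, paste0(sid, ".csv"))
    rec <- tryCatch(read_recording_csv(p, subjects[i, ]),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      problems <- c(problems, sprintf("%s: %s", p, rec))
    } else {
      recordings[[length(recordings) + 1L]] <- rec
    }
  }
  tab <- extract_cohort_features(recordings, specs, qrs_opts, fid_opts,
                                 min_beats)
  write_feature_table(tab, out_path)
  log_path <- sub("\\.csv$", "_log.txt", out_path)
  writeLines(c(sprintf("subjects read: %d", nrow(subjects)),
               sprintf("subjects retained: %d", nrow(tab)),
               problems, attr(tab, "exclusions")), log_path)
  invisible(tab)
}

#' Analyze a cohort feature table
#'
#' Runs the comparison battery and the normalized-latency sex comparison,
#' writing the tidy battery CSV, a markdown grid, and a summary report.
#'
#' @param features Feature table (tibble) or path to one written by
#'   [write_feature_table()].
#' @param out_dir Output directory.
#' @param cfg A [stats_config()].
#' @return List with `battery` and `sex_summary`, invisibly.
#' @export
cmd_analyze <- function(features, out_dir, cfg = stats_config()) {
  if (is.character(features)) features <- read_feature_table(features)
  schema <- attr(features, "ppgcohort_schema")
  if (!is.null(schema) && !identical(schema, feature_schema_version())) {
    stop(sprintf("unrecognized feature-table schema '%s'", schema),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  battery <- run_battery(features, cfg)
  readr::write_csv(battery, file.path(out_dir, "battery.csv"))
  writeLines(format_battery_grid(battery),
             file.path(out_dir, "battery_grid.md"))
  sexsum <- sex_latency_summary(features, cfg)
  readr::write_csv(sexsum, file.path(out_dir, "sex_latency_summary.csv"))
  skipped <- attr(battery, "skipped")
  writeLines(c(sprintf("comparisons run: %d", nrow(battery)),
               sprintf("significant (p < %g and r2 > %g): %d", cfg$alpha,
                       cfg$r2_min, sum(battery$significant)),
               if (length(skipped)) c("skipped:", paste(" ", skipped))),
             file.path(out_dir, "analysis_log.txt"))
  invisible(list(battery = battery, sex_summary = sexsum))
}
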