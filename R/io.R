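# Waveform and cohort-table I/O plus the cohort cleansing rules:
# ECG-to-LVM matching within a time window, redundancy resolution,
# rhythm/sex exclusions, and training-median imputation.

#' Construct an ECG record
#'
#' @param waveform `L x 12` numeric matrix, millivolts, time-major; columns
#'   are reordered into the canonical lead order (see [ecg_leads()]) by
#'   name.
#' @param fs Sampling rate, Hz.
#' @param record_id Identifier string.
#' @param acquired_at Acquisition timestamp (ISO-8601 string), optional.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(waveform, fs = 500, record_id = "rec",
                       acquired_at = NA_character_) {
  waveform <- canonicalize_leads(as.matrix(waveform), record_id)
  if (anyNA(waveform)) stop("record ", record_id, ": waveform contains NA")
  if (fs <= 0) stop("fs must be positive")
  structure(list(record_id = record_id, waveform = waveform, fs = fs,
                 lead_names = ecg_leads(), acquired_at = acquired_at),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record %s: %d samples x 12 leads @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$waveform), x$fs, nrow(x$waveform) / x$fs))
  invisible(x)
}

#' Construct a synchronized single-beat segment
#'
#' @param waveform `W x 12` matrix, millivolts, identical sample range for
#'   all 12 leads (synchrony).
#' @param fs Sampling rate, Hz.
#' @param r_index 0-based sample offset of the R peak within the window.
#' @param landmarks Optional named integer vector (`p_onset`, `qrs_onset`,
#'   `qrs_offset`, `t_offset`), 0-based sample offsets; must satisfy
#'   `p_onset < qrs_onset <= r_index <= qrs_offset < t_offset` and lie in
#'   `[0, W)`.
#' @param source_record_id Originating record id.
#' @param flagged Logical; `TRUE` when landmark delineation failed and
#'   fixed-offset fallback landmarks were substituted.
#' @return Object of class `beat_segment`.
#' @export
beat_segment <- function(waveform, fs, r_index, landmarks = NULL,
                         source_record_id = NA_character_, flagged = FALSE) {
  waveform <- canonicalize_leads(as.matrix(waveform), source_record_id)
  W <- nrow(waveform)
  if (!is.null(landmarks)) {
    need <- c("p_onset", "qrs_onset", "qrs_offset", "t_offset")
    stopifnot(setequal(names(landmarks), need))
    landmarks <- as.integer(landmarks[need])
    names(landmarks) <- need
    if (any(landmarks < 0) || any(landmarks >= W)) {
      stop("landmarks must lie in [0, W)")
    }
    ok <- landmarks[["p_onset"]] <= landmarks[["qrs_onset"]] &&
      landmarks[["qrs_onset"]] <= r_index &&
      r_index <= landmarks[["qrs_offset"]] &&
      landmarks[["qrs_offset"]] < landmarks[["t_offset"]]
    if (!ok) stop("landmark ordering violated: need p_onset <= qrs_onset <= ",
                  "r_index <= qrs_offset < t_offset")
  }
  structure(list(waveform = waveform, fs = fs, r_index = as.integer(r_index),
                 landmarks = landmarks, source_record_id = source_record_id,
                 flagged = flagged),
            class = "beat_segment")
}

#' @export
print.beat_segment <- function(x, ...) {
  cat(sprintf("Beat segment (%s): %d samples x 12 leads @ %g Hz, R at %d%s\n",
              x$source_record_id, nrow(x$waveform), x$fs, x$r_index,
              if (is.null(x$landmarks)) ", no landmarks"
              else if (x$flagged) ", fallback landmarks" else ""))
  invisible(x)
}

#' Write ECG waveforms to a CSV store
#'
#' One CSV per record (columns = canonical leads, values in millivolts,
#' printed with 17 significant digits so the round trip is exact) plus an
#' `records.csv` index with `record_id`, `fs` and `acquired_at`.
#'
#' @param records List of [ecg_record] objects.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_waveforms <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(
    record_id = vapply(records, `[[`, "", "record_id"),
    fs = vapply(records, `[[`, 0, "fs"),
    acquired_at = vapply(records, function(r) as.character(r$acquired_at), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(idx, file.path(dir, "records.csv"), row.names = FALSE)
  for (r in records) {
    df <- as.data.frame(format(r$waveform, digits = 17, trim = TRUE,
                               scientific = TRUE))
    utils::write.csv(df, file.path(dir, paste0(r$record_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load ECG waveforms
#'
#' Reads a waveform store into a list of [ecg_record]s, enforcing the
#' canonical 12-lead order (records are reordered by lead name; a missing
#' or unknown lead is an error naming the record). Only the package's CSV
#' container is implemented; `"wfdb"` and `"hdf5"` are declared plugin
#' points and rejected with an informative error.
#'
#' @param path Directory produced by [write_waveforms()].
#' @param format Container format; only `"csv"` is available.
#' @return List of [ecg_record] objects, in index order.
#' @export
load_waveforms <- function(path, format = c("csv", "wfdb", "hdf5")) {
  format <- match.arg(format)
  if (format != "csv") {
    stop("format '", format, "' is a declared plugin point; no reader is ",
         "bundled. Use the CSV container (write_waveforms/load_waveforms).")
  }
  idx <- utils::read.csv(file.path(path, "records.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    f <- file.path(path, paste0(idx$record_id[i], ".csv"))
    if (!file.exists(f)) stop("missing waveform file for record ",
                              idx$record_id[i])
    wf <- as.matrix(utils::read.csv(f, check.names = FALSE))
    ecg_record(wf, fs = idx$fs[i], record_id = idx$record_id[i],
               acquired_at = idx$acquired_at[i])
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort table (`cohort.csv`), the ground-truth fiducials
#' sidecar (`fiducials.csv`: record_id, beat_index, landmark, sample) and
#' the waveform CSV store under `waveforms/`.
#'
#' @param cohort An `ecg_cohort` (waveforms are regenerated if not stored).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$rows, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$fiducials, file.path(dir, "fiducials.csv"),
                   row.names = FALSE)
  recs <- lapply(seq_len(nrow(cohort$rows)), function(i)
    cohort_record(cohort, i))
  write_waveforms(recs, file.path(dir, "waveforms"))
  invisible(dir)
}

#' Read a cohort table
#'
#' @param path Path to a cohort CSV (one row per patient/record pair, with
#'   the `CohortRow` columns; timestamps ISO-8601).
#' @return `data.frame`.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

parse_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Match ECGs to LVM measurements within a time window
#'
#' Keeps ECG rows acquired within `window_days` of the patient's CT-derived
#' LVM measurement and resolves redundancy (several ECGs matched to one LVM
#' value): the ECG closest in time is kept, ties broken by the earliest
#' ECG. Rows lacking a timestamp are dropped as unmatchable.
#'
#' @param rows Cohort `data.frame` with `patient_id`, `record_id`,
#'   `ct_time`, `ecg_time` (ISO-8601 strings or POSIXct).
#' @param window_days Matching window, days; default 183 (six months).
#' @return List with `rows` (kept) and `log` (`data.frame` of
#'   `record_id`, `rule` in `window`/`redundant`/`unmatchable`).
#' @export
match_ecg_to_lvm <- function(rows, window_days = 183) {
  if (nrow(rows) == 0) {
    return(list(rows = rows,
                log = data.frame(record_id = character(),
                                 rule = character())))
  }
  ct <- if (inherits(rows$ct_time, "POSIXct")) rows$ct_time else parse_time(rows$ct_time)
  ecg <- if (inherits(rows$ecg_time, "POSIXct")) rows$ecg_time else parse_time(rows$ecg_time)
  diff_days <- abs(as.numeric(difftime(ecg, ct, units = "days")))
  rule <- rep(NA_character_, nrow(rows))
  rule[is.na(diff_days)] <- "unmatchable"
  rule[is.na(rule) & diff_days > window_days] <- "window"
  for (pid in unique(rows$patient_id)) {
    cand <- which(rows$patient_id == pid & is.na(rule))
    if (length(cand) > 1) {
      best <- cand[order(diff_days[cand], as.numeric(ecg[cand]))][1]
      rule[setdiff(cand, best)] <- "redundant"
    }
  }
  keep <- is.na(rule)
  list(rows = rows[keep, , drop = FALSE],
       log = data.frame(record_id = rows$record_id[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Apply rhythm and sex exclusions
#'
#' Drops rows with any rhythm exclusion flag (bundle branch block, paced
#' rhythm, atrial fibrillation) or unknown sex, logging the reason.
#'
#' @param rows Cohort `data.frame` with `rhythm_flags` (semicolon-separated
#'   subset of `bbb`, `paced`, `afib`; empty string for none) and `sex`.
#' @return List with `rows` (kept) and `log` (`record_id`, `rule`).
#' @export
apply_rhythm_exclusions <- function(rows) {
  flags <- ifelse(is.na(rows$rhythm_flags), "", rows$rhythm_flags)
  bad_flag <- nzchar(trimws(flags))
  bad_sex <- !(rows$sex %in% c("male", "female"))
  rule <- ifelse(bad_flag, flags, ifelse(bad_sex, "unknown sex", NA))
  keep <- is.na(rule)
  list(rows = rows[keep, , drop = FALSE],
       log = data.frame(record_id = rows$record_id[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

# numeric covariate columns subject to imputation (never the target)
scalar_columns <- function() {
  c("age", "height", "weight", "qrs_duration", "p_axis", "r_axis", "t_axis")
}

#' Impute missing scalars with training medians
#'
#' Replaces missing numeric covariates by the column median computed on the
#' training rows only, so held-out rows never contribute to the statistics
#' (no leakage). Idempotent: with no missing values the rows are returned
#' unchanged and the report is empty. The ground-truth LVM is never
#' imputed.
#'
#' @param rows Cohort `data.frame`.
#' @param train_ids Integer row indices defining the training partition on
#'   which medians are computed; defaults to all rows.
#' @param columns Numeric columns to impute (default: the scalar
#'   covariates).
#' @return List with `rows` (no missing numerics in `columns`) and
#'   `report` (`data.frame` of `column`, `median`, `n_imputed`).
#' @export
impute_scalars <- function(rows, train_ids = seq_len(nrow(rows)),
                           columns = intersect(scalar_columns(),
                                               names(rows))) {
  rep_rows <- list()
  for (cl in columns) {
    train_vals <- rows[[cl]][train_ids]
    if (all(is.na(train_vals))) {
      stop("column '", cl, "' has no observed training values to impute from")
    }
    med <- stats::median(train_vals, na.rm = TRUE)
    miss <- is.na(rows[[cl]])
    if (any(miss)) {
      rows[[cl]][miss] <- med
      rep_rows[[cl]] <- data.frame(column = cl, median = med,
                                   n_imputed = sum(miss),
                                   stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(column = character(), median = numeric(),
               n_imputed = integer())
  rownames(report) <- NULL
  list(rows = rows, report = report)
}

#' Left ventricular mass from myocardial volume
#'
#' Converts a CT-segmented LV myocardium volume to mass using the
#' myocardial density 1.05 g/mL.
#'
#' @param volume_ml Volume in millilitres (>= 0; vectorized).
#' @return Mass in grams: `volume_ml * 1.05`.
#' @examples
#' lvm_from_volume(100)  # 105 g
#' @export
lvm_from_volume <- function(volume_ml) {
  if (any(volume_ml < 0)) stop("volume must be non-negative")
  volume_ml * 1.05
}
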