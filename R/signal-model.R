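## Domain containers: recordings, beat series, per-beat systolic pressures,
## breath series, threshold specifications, cohort tables.

#' Multichannel physiological recording
#'
#' Container for a simultaneous ECG / arterial blood pressure / respiration
#' recording with a single uniform sampling rate. All channels must have the
#' same length. The nominal protocol is a 30-minute supine resting recording;
#' any duration of at least 600 s is accepted (the respiration-rate marker
#' needs a final 10-minute window; shorter recordings make individual markers
#' "not evaluable" rather than failing outright).
#'
#' @param ecg numeric matrix of ECG samples in mV, one column per lead.
#'   Column names name the leads; orthogonal `X`, `Y`, `Z` are the
#'   conventional set, but a single-lead matrix is accepted.
#' @param bp numeric vector, continuous arterial pressure in mmHg.
#' @param resp numeric vector, thoracic respiration signal (arbitrary units).
#' @param fs sampling frequency in Hz (shared by all channels).
#' @param subject_id opaque subject identifier string.
#' @param recorded_state free-text acquisition metadata, e.g. "supine resting".
#'
#' @return An object of class `polyscore_recording` with fields `ecg`, `bp`,
#'   `resp`, `fs`, `n`, `duration_s`, `subject_id`, `recorded_state`.
#' @examples
#' fs <- 200
#' t <- seq(0, 10 - 1 / fs, by = 1 / fs)
#' rec <- recording(
#'   ecg = cbind(X = sin(2 * pi * t)), bp = 80 + 40 * abs(sin(pi * t)),
#'   resp = sin(2 * pi * 0.25 * t), fs = fs
#' )
#' rec$duration_s
#' @export
recording <- function(ecg, bp, resp, fs, subject_id = "anonymous",
                      recorded_state = "supine resting") {
  if (is.null(dim(ecg))) ecg <- cbind(X = as.numeric(ecg))
  ecg <- as.matrix(ecg)
  if (is.null(colnames(ecg))) {
    colnames(ecg) <- c("X", "Y", "Z")[seq_len(ncol(ecg))]
  }
  bp <- as.numeric(bp)
  resp <- as.numeric(resp)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  n <- nrow(ecg)
  if (length(bp) != n || length(resp) != n) {
    stop(sprintf(
      "channel lengths differ: ecg %d, bp %d, resp %d samples",
      n, length(bp), length(resp)
    ))
  }
  structure(
    list(
      ecg = ecg, bp = bp, resp = resp, fs = fs, n = n,
      duration_s = n / fs,
      subject_id = as.character(subject_id),
      recorded_state = as.character(recorded_state)
    ),
    class = "polyscore_recording"
  )
}

#' @export
print.polyscore_recording <- function(x, ...) {
  cat(sprintf(
    "<polyscore_recording> subject '%s': %d samples @ %g Hz (%.1f s), leads %s\n",
    x$subject_id, x$n, x$fs, x$duration_s,
    paste(colnames(x$ecg), collapse = "/")
  ))
  invisible(x)
}

#' Beat series: R-peak times, RR intervals and beat labels
#'
#' Ordered R-peak times with one label per beat. Labels follow WFDB-style
#' symbols: `N` normal sinus, `V` ventricular ectopic, `S` supraventricular
#' ectopic, `X` artifact / unclassifiable. RR intervals are derived: the
#' interval `rr_ms[i]` (in ms) belongs to the beat that terminates it, i.e.
#' beat `i + 1`.
#'
#' @param beat_times_s strictly increasing R-peak times in seconds from
#'   recording start.
#' @param labels character vector of per-beat symbols, recycled from "N" if
#'   omitted. Unknown symbols are mapped to `X` with a warning.
#'
#' @return Object of class `beat_series` with fields `beat_times_s`, `labels`,
#'   `rr_ms` (length `n_beats - 1`), `n_beats`.
#' @examples
#' bs <- beat_series(c(0, 0.8, 1.6, 2.2, 3.2), c("N", "N", "N", "V", "N"))
#' bs$rr_ms
#' @export
beat_series <- function(beat_times_s, labels = NULL) {
  beat_times_s <- as.numeric(beat_times_s)
  n <- length(beat_times_s)
  if (n > 1 && any(diff(beat_times_s) <= 0)) {
    stop("beat_times_s must be strictly increasing")
  }
  if (is.null(labels)) labels <- rep("N", n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per beat")
  known <- labels %in% c("N", "V", "S", "X")
  if (any(!known)) {
    warning(sprintf(
      "%d unknown beat symbol(s) (%s) mapped to X",
      sum(!known), paste(unique(labels[!known]), collapse = ",")
    ))
    labels[!known] <- "X"
  }
  structure(
    list(
      beat_times_s = beat_times_s,
      labels = labels,
      rr_ms = if (n > 1) 1000 * diff(beat_times_s) else numeric(0),
      n_beats = n
    ),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("N", "V", "S", "X")))
  cat(sprintf(
    "<beat_series> %d beats (%s), span %.1f s\n",
    x$n_beats,
    paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
    if (x$n_beats > 1) diff(range(x$beat_times_s)) else 0
  ))
  invisible(x)
}

#' Per-beat systolic blood pressure series
#'
#' Beat-aligned systolic pressures with a per-beat validity flag. Values
#' outside the plausibility window (50-250 mmHg by default) are retained but
#' flagged invalid rather than deleted, so beat alignment with the
#' [beat_series()] is preserved.
#'
#' @param values_mmHg per-beat systolic pressures in mmHg (NA allowed).
#' @param beat_index integer indices into the parent beat series
#'   (default `seq_along(values_mmHg)`).
#' @param valid_mask logical per-beat quality flag; by default computed from
#'   the plausibility window.
#' @param plausible numeric length-2, plausibility window in mmHg.
#' @return Object of class `sbp_series`.
#' @export
sbp_series <- function(values_mmHg, beat_index = seq_along(values_mmHg),
                       valid_mask = NULL, plausible = c(50, 250)) {
  values_mmHg <- as.numeric(values_mmHg)
  beat_index <- as.integer(beat_index)
  if (length(beat_index) != length(values_mmHg)) {
    stop("beat_index must align with values_mmHg")
  }
  if (is.null(valid_mask)) {
    valid_mask <- is.finite(values_mmHg) &
      values_mmHg >= plausible[1] & values_mmHg <= plausible[2]
  }
  if (length(valid_mask) != length(values_mmHg)) {
    stop("valid_mask must align with values_mmHg")
  }
  structure(
    list(
      values_mmHg = values_mmHg, beat_index = beat_index,
      valid_mask = as.logical(valid_mask)
    ),
    class = "sbp_series"
  )
}

#' Breath series: inspiration and expiration onset times
#'
#' @param breath_onset_times_s strictly increasing breath (inspiration) onset
#'   times in seconds.
#' @param expiration_onset_times_s strictly increasing expiration onset times
#'   (end-inspiration landmarks); must interleave the breath onsets.
#' @return Object of class `breath_series`.
#' @export
breath_series <- function(breath_onset_times_s, expiration_onset_times_s) {
  b <- as.numeric(breath_onset_times_s)
  e <- as.numeric(expiration_onset_times_s)
  if (length(b) > 1 && any(diff(b) <= 0)) {
    stop("breath onsets must be strictly increasing")
  }
  if (length(e) > 1 && any(diff(e) <= 0)) {
    stop("expiration onsets must be strictly increasing")
  }
  structure(
    list(breath_onset_times_s = b, expiration_onset_times_s = e),
    class = "breath_series"
  )
}

#' Dichotomy threshold specification for one marker
#'
#' Records where a marker's abnormal side lies. `abnormal_side` semantics:
#' `"below_or_equal"` means values `<= threshold` are abnormal,
#' `"at_or_above"` means `>= threshold`, `"above"` means strictly `>`.
#' For the ectopy marker the threshold is a named pair
#' `c(sve = ..., ve = ...)` and the marker is abnormal when either count
#' strictly exceeds its limit.
#'
#' @param marker_name marker identifier (e.g. "TS").
#' @param threshold_value numeric threshold (named pair for ECTOPY).
#' @param units unit string.
#' @param abnormal_side one of "below_or_equal", "at_or_above", "above".
#' @param source free-text citation / provenance string.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(marker_name, threshold_value, units,
                           abnormal_side = c("below_or_equal", "at_or_above", "above"),
                           source = "") {
  abnormal_side <- match.arg(abnormal_side)
  if (!all(is.finite(threshold_value))) stop("threshold must be finite")
  structure(
    list(
      marker_name = marker_name, threshold_value = threshold_value,
      units = units, abnormal_side = abnormal_side, source = source
    ),
    class = "threshold_spec"
  )
}

#' Default marker dichotomies
#'
#' The seven published cutoffs used by the Polyscore: turbulence slope
#' \eqn{\le} 2.5 ms/RR, deceleration capacity \eqn{\le} 2.5 ms, baroreflex
#' sensitivity \eqn{\le} 1.58 ms/mmHg, respiration rate \eqn{\ge} 18.6
#' breaths/min, expiration-triggered sinus arrhythmia \eqn{\le} 0.19 ms,
#' post-ectopic potentiation ratio \eqn{\ge} 1.03, and ectopy counts
#' strictly > 7 supraventricular or > 29 ventricular ectopics per 30 min.
#'
#' @return Named list of [threshold_spec()] objects.
#' @export
default_thresholds <- function() {
  list(
    TS = threshold_spec("TS", 2.5, "ms/RR", "below_or_equal",
      "established HRT slope dichotomy"
    ),
    DC = threshold_spec("DC", 2.5, "ms", "below_or_equal",
      "established deceleration-capacity dichotomy"
    ),
    BRS = threshold_spec("BRS", 1.58, "ms/mmHg", "below_or_equal",
      "established PRSA baroreflex-sensitivity dichotomy"
    ),
    RESP = threshold_spec("RESP", 18.6, "breaths/min", "at_or_above",
      "resting respiration rate dichotomy"
    ),
    ETA = threshold_spec("ETA", 0.19, "ms", "below_or_equal",
      "expiration-triggered sinus arrhythmia dichotomy"
    ),
    PESP = threshold_spec("PESP", 1.03, "ratio", "at_or_above",
      "post-ectopic potentiation presence dichotomy"
    ),
    ECTOPY = threshold_spec("ECTOPY", c(sve = 7, ve = 29), "count/30min",
      "above", "log-rank-optimized ectopy count dichotomies"
    )
  )
}

#' Cohort table of per-patient survival records
#'
#' Validates and classes a per-patient follow-up table. Required columns:
#' `subject_id`, `followup_days` (> 0), `event` (0/1 death indicator),
#' `polyscore` (integer 0-7 or NA). Optional: `lvef_percent`, `diabetes`
#' (0/1), `grace_score`, and seven marker flag columns `flag_ts`, `flag_dc`,
#' `flag_brs`, `flag_resp`, `flag_eta`, `flag_pesp`, `flag_ectopy` (0/1).
#' When both `polyscore` and all seven flags are present, the score must
#' equal the flag sum.
#'
#' @param df data.frame with the columns above.
#' @return `df` with class `polyscore_cohort` prepended.
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df)
  required <- c("subject_id", "followup_days", "event", "polyscore")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf(
      "event must be 0 or 1; offending row(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(df$followup_days) | df$followup_days <= 0)
  if (length(bad)) {
    stop(sprintf(
      "followup_days must be > 0; offending row(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  bad <- which(!is.na(df$polyscore) &
    (df$polyscore < 0 | df$polyscore > 7 | df$polyscore != round(df$polyscore)))
  if (length(bad)) {
    stop(sprintf(
      "polyscore must be an integer in 0..7; offending row(s): %s",
      paste(head(bad, 10), collapse = ", ")
    ))
  }
  fl <- marker_flag_columns()
  if (all(fl %in% names(df))) {
    fs <- rowSums(df[fl])
    bad <- which(!is.na(df$polyscore) & !is.na(fs) & fs != df$polyscore)
    if (length(bad)) {
      stop(sprintf(
        "polyscore inconsistent with marker flag sum; offending row(s): %s",
        paste(head(bad, 10), collapse = ", ")
      ))
    }
  }
  class(df) <- c("polyscore_cohort", class(df))
  df
}

marker_flag_columns <- function() {
  c("flag_ts", "flag_dc", "flag_brs", "flag_resp", "flag_eta", "flag_pesp",
    "flag_ectopy")
}

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, mandatory header; empty fields are missing values.
#' See [cohort_table()] for the column contract; validation failures are
#' reported with row numbers.
#'
#' @param path CSV file path.
#' @return A validated `polyscore_cohort` data.frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  cohort_table(df)
}

#' Write a cohort CSV
#' @param cohort a `polyscore_cohort` (or compatible data.frame).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
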