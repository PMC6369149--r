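## The Polyscore itself: count of abnormal markers, risk class mapping,
## and end-to-end per-recording orchestration.

#' Polyscore from seven marker flags
#'
#' The Polyscore is the number of abnormal results among the seven
#' dichotomized markers, an integer 0 (all normal) to 7 (all abnormal).
#' Flags must all be resolved (the no-VPC policy is applied upstream).
#'
#' @param flags logical/0-1 vector of length 7, optionally named.
#' @param weights optional non-negative weight vector (defaults to ones;
#'   the canonical Polyscore is unweighted).
#' @return integer (numeric when non-unit weights are supplied).
#' @export
compute_polyscore <- function(flags, weights = rep(1, 7)) {
  if (length(flags) != 7) stop("the Polyscore needs exactly 7 marker flags")
  if (any(is.na(flags))) {
    nm <- names(flags)
    bad <- which(is.na(flags))
    lab <- if (!is.null(nm)) paste(nm[bad], collapse = ", ") else
      paste(bad, collapse = ", ")
    stop("unresolved marker flag(s): ", lab)
  }
  s <- sum(as.numeric(flags) * weights)
  if (all(weights == 1)) as.integer(s) else s
}

#' Risk class from a Polyscore
#'
#' Low risk for scores <= 2, intermediate for 3 or 4, high for >= 5.
#'
#' @param score integer 0-7.
#' @return factor level among `"low"`, `"intermediate"`, `"high"`.
#' @export
classify_risk <- function(score) {
  if (any(score < 0 | score > 7 | score != round(score))) {
    stop("score must be an integer in 0..7")
  }
  cls <- ifelse(score <= 2, "low", ifelse(score <= 4, "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Analysis configuration
#'
#' Bundles the tunables of the per-recording pipeline: PRSA settings,
#' marker thresholds, beat-classification parameters, and the no-VPC
#' policy (what a recording without eligible ventricular premature beats
#' contributes for TS and PESP: `"normal"` scores them 0, `"exclude"`
#' flags the analysis incomplete).
#'
#' @param prsa a [prsa_config()].
#' @param thresholds named list of [threshold_spec()]s.
#' @param no_vpc_policy `"normal"` or `"exclude"`.
#' @param qrs_wide_ms,prematurity_frac,compensatory_tol see
#'   [classify_beats()].
#' @return list of class `polyscore_config`.
#' @export
polyscore_config <- function(prsa = prsa_config(),
                             thresholds = default_thresholds(),
                             no_vpc_policy = c("normal", "exclude"),
                             qrs_wide_ms = 120, prematurity_frac = 0.8,
                             compensatory_tol = 0.1) {
  structure(
    list(
      prsa = prsa, thresholds = thresholds,
      no_vpc_policy = match.arg(no_vpc_policy),
      qrs_wide_ms = qrs_wide_ms, prematurity_frac = prematurity_frac,
      compensatory_tol = compensatory_tol
    ),
    class = "polyscore_config"
  )
}

resolve_flags <- function(markers, no_vpc_policy) {
  flags <- vapply(markers, function(m) {
    if (m$evaluable) m$abnormal else NA
  }, logical(1))
  unresolved <- names(flags)[is.na(flags)]
  if (no_vpc_policy == "normal") {
    for (nm in intersect(unresolved, c("TS", "PESP"))) flags[nm] <- FALSE
    unresolved <- setdiff(unresolved, c("TS", "PESP"))
  }
  list(flags = flags, unresolved = unresolved)
}

#' End-to-end Polyscore analysis of one recording
#'
#' Runs the full chain: beat detection and classification, artifact
#' filtering, systolic pressure extraction, breath detection, the seven
#' markers, and the Polyscore with its risk class. Deterministic for a
#' fixed recording and configuration.
#'
#' @param rec a [recording()].
#' @param config a [polyscore_config()].
#' @param annotations optional externally curated [beat_series()]; when
#'   supplied, beat detection is skipped.
#' @return Object of class `polyscore_result`: fields `markers` (list of 7
#'   `marker_result`s), `flags`, `score`, `risk_class`, `incomplete`,
#'   `not_evaluable_markers`, `beats`, `sbp`, `breaths`, `provenance`.
#' @export
analyze_recording <- function(rec, config = polyscore_config(),
                              annotations = NULL) {
  stopifnot(inherits(rec, "polyscore_recording"))
  bs <- if (!is.null(annotations)) {
    annotations
  } else {
    detect_beats(rec,
      qrs_wide_ms = config$qrs_wide_ms,
      prematurity_frac = config$prematurity_frac,
      compensatory_tol = config$compensatory_tol
    )
  }
  sbp <- extract_systolic_pressures(rec$bp, bs$beat_times_s, rec$fs)
  breaths <- detect_breaths(rec$resp, rec$fs)
  markers <- compute_markers(bs, sbp, breaths, rec$duration_s,
    config = config$prsa, thresholds = config$thresholds
  )
  res <- resolve_flags(markers, config$no_vpc_policy)
  incomplete <- length(res$unresolved) > 0
  score <- if (incomplete) NA_integer_ else compute_polyscore(res$flags)
  structure(
    list(
      markers = markers,
      flags = res$flags,
      score = score,
      risk_class = if (incomplete) NA else classify_risk(score),
      incomplete = incomplete,
      not_evaluable_markers = res$unresolved,
      beats = bs, sbp = sbp, breaths = breaths,
      provenance = list(
        subject_id = rec$subject_id,
        fs = rec$fs, duration_s = rec$duration_s,
        config = config,
        package_version = as.character(packageVersion("polyscore"))
      )
    ),
    class = "polyscore_result"
  )
}

#' @export
print.polyscore_result <- function(x, ...) {
  cat("<polyscore_result>", x$provenance$subject_id, "\n")
  print(marker_report(x$markers))
  if (x$incomplete) {
    cat(
      "INCOMPLETE: not evaluable:",
      paste(x$not_evaluable_markers, collapse = ", "), "\n"
    )
  } else {
    cat(sprintf("Polyscore %d -> %s risk\n", x$score,
      as.character(x$risk_class)))
  }
  invisible(x)
}

#' Serialize a Polyscore result to JSON
#'
#' @param result a `polyscore_result`.
#' @param path optional destination; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
polyscore_report_json <- function(result, path = NULL) {
  payload <- list(
    subject_id = result$provenance$subject_id,
    score = result$score,
    risk_class = as.character(result$risk_class),
    incomplete = result$incomplete,
    not_evaluable_markers = result$not_evaluable_markers,
    markers = lapply(result$markers, function(m) {
      list(
        name = m$name, value = m$value, units = m$units,
        threshold = m$threshold$threshold_value,
        abnormal_side = m$threshold$abnormal_side,
        abnormal = m$abnormal, evaluable = m$evaluable,
        n_support = m$n_support
      )
    }),
    package_version = result$provenance$package_version
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
    null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
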