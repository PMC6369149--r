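## Phase-rectified signal averaging (PRSA), univariate and bivariate.
## Anchors are selected by a criterion in one series; windows of another
## (or the same) series are aligned at the anchors and averaged. The
## quartet measure (X(0)+X(1)-X(-1)-X(-2))/4 summarizes the averaged
## window into the scalar used by DC, BRS and ETA.

#' PRSA configuration
#'
#' @param half_window_L half window length in beats; the averaged window
#'   covers offsets `-L .. L-1` around each anchor.
#' @param max_relative_increase upper eligibility bound for RR-increase
#'   anchors: an increase beyond this fraction of the previous interval is
#'   considered non-physiological (ectopy, artifact) and skipped.
#' @param min_anchors minimum anchor count below which a PRSA-based marker
#'   is reported "not evaluable".
#' @return A list of class `prsa_config`.
#' @export
prsa_config <- function(half_window_L = 20, max_relative_increase = 0.05,
                        min_anchors = 5) {
  stopifnot(half_window_L >= 2, max_relative_increase > 0,
    max_relative_increase <= 1)
  structure(
    list(
      half_window_L = as.integer(half_window_L),
      max_relative_increase = max_relative_increase,
      min_anchors = as.integer(min_anchors),
      quartet_offsets = c(0L, 1L, -1L, -2L)
    ),
    class = "prsa_config"
  )
}

#' Select PRSA anchor indices
#'
#' Two built-in criteria: `"rr_increase"` selects indices `i` with
#' `x[i] > x[i-1]` and `x[i] <= (1 + max_relative_increase) * x[i-1]`
#' (deceleration anchors with an eligibility ceiling); `"bp_rise"` selects
#' `x[i] > x[i-1]` (systolic pressure rises). Anchors without a full
#' `-L .. L-1` window, or excluded by `valid_mask`, are dropped.
#'
#' @param x numeric series (RR in ms, or SBP in mmHg).
#' @param criterion `"rr_increase"` or `"bp_rise"`.
#' @param config a [prsa_config()].
#' @param valid_mask optional logical mask; anchors must sit at `TRUE`
#'   positions (used to keep anchors away from ectopic beats).
#' @return integer vector of anchor indices (possibly empty).
#' @export
select_anchors <- function(x, criterion = c("rr_increase", "bp_rise"),
                           config = prsa_config(), valid_mask = NULL) {
  criterion <- match.arg(criterion)
  n <- length(x)
  L <- config$half_window_L
  if (n <= 2 * L) return(integer(0))
  i <- 2:n
  sel <- x[i] > x[i - 1]
  if (criterion == "rr_increase") {
    sel <- sel & x[i] <= (1 + config$max_relative_increase) * x[i - 1]
  }
  idx <- i[sel]
  idx <- idx[idx - L >= 1 & idx + L - 1 <= n]
  if (!is.null(valid_mask)) idx <- idx[valid_mask[idx]]
  idx
}

#' Phase-rectified average around anchors
#'
#' `X(k) = mean over anchors i of target[i + k]`, for `k = -L .. L-1`.
#'
#' @param target numeric target series.
#' @param anchor_indices integer anchor positions (each must have a full
#'   window inside the series).
#' @param L half window length.
#' @return A list of class `prsa_result` with fields `X` (named by offset),
#'   `offsets`, `n_anchors`, `anchor_indices`, `evaluable`.
#' @export
prsa_average <- function(target, anchor_indices, L = 20) {
  offsets <- -L:(L - 1)
  if (!length(anchor_indices)) {
    return(structure(
      list(
        X = setNames(rep(NA_real_, length(offsets)), offsets),
        offsets = offsets, n_anchors = 0L, anchor_indices = integer(0),
        evaluable = FALSE
      ),
      class = "prsa_result"
    ))
  }
  if (any(anchor_indices - L < 1) || any(anchor_indices + L - 1 > length(target))) {
    stop("anchor without a full window")
  }
  idx <- outer(anchor_indices, offsets, `+`)
  X <- colMeans(matrix(target[idx], nrow = length(anchor_indices)))
  structure(
    list(
      X = setNames(X, offsets), offsets = offsets,
      n_anchors = length(anchor_indices),
      anchor_indices = as.integer(anchor_indices),
      evaluable = TRUE
    ),
    class = "prsa_result"
  )
}

#' @export
print.prsa_result <- function(x, ...) {
  cat(sprintf(
    "<prsa_result> %d anchors, window %d..%d, quartet %.4g\n",
    x$n_anchors, min(x$offsets), max(x$offsets),
    quartet_measure(x)
  ))
  invisible(x)
}

#' Quartet measure of an averaged PRSA window
#'
#' The scalar `(X(0) + X(1) - X(-1) - X(-2)) / 4`, i.e. the central
#' difference of the phase-rectified average across the anchor, in the
#' units of the target series. Returns `NA` for a non-evaluable input.
#'
#' @param prsa_result a [prsa_average()] result.
#' @return numeric scalar.
#' @export
quartet_measure <- function(prsa_result) {
  if (!prsa_result$evaluable) return(NA_real_)
  X <- prsa_result$X
  k <- as.character(c(0, 1, -1, -2))
  if (!all(k %in% names(X))) stop("quartet needs offsets -2..1 in the window")
  unname((X["0"] + X["1"] - X["-1"] - X["-2"]) / 4)
}

#' Map event times to beat indices
#'
#' Each event is mapped to the first beat at or after the event time;
#' events past the last beat are dropped.
#'
#' @param event_times_s numeric event times (s).
#' @param beat_times_s strictly increasing beat times (s).
#' @return integer vector of beat indices.
#' @export
events_to_beat_indices <- function(event_times_s, beat_times_s) {
  idx <- findInterval(event_times_s, beat_times_s, left.open = TRUE) + 1L
  idx[idx <= length(beat_times_s)]
}

#' Bivariate phase-rectified signal averaging
#'
#' Anchors are defined in one signal and averaging is applied to another.
#' Two anchoring modes: a beat-aligned anchor series (e.g. systolic
#' pressures; anchors are its rises), or event times (e.g. expiration
#' onsets; each mapped to the first beat at or after the event). Anchors
#' without full windows in the target are dropped.
#'
#' @param target numeric beat-aligned target series (typically RR in ms).
#' @param anchor_series optional beat-aligned series to take `bp_rise`
#'   anchors from.
#' @param event_times_s optional event times; used when `anchor_series` is
#'   `NULL`.
#' @param beat_times_s beat times, required with `event_times_s`.
#' @param config a [prsa_config()].
#' @param valid_mask optional anchor eligibility mask over beats.
#' @return A `prsa_result`.
#' @export
bivariate_prsa <- function(target, anchor_series = NULL, event_times_s = NULL,
                           beat_times_s = NULL, config = prsa_config(),
                           valid_mask = NULL) {
  L <- config$half_window_L
  if (!is.null(anchor_series)) {
    if (length(anchor_series) != length(target)) {
      stop("anchor_series must align with target")
    }
    anchors <- select_anchors(anchor_series, "bp_rise", config, valid_mask)
  } else if (!is.null(event_times_s)) {
    if (is.null(beat_times_s)) stop("event anchoring needs beat_times_s")
    anchors <- events_to_beat_indices(event_times_s, beat_times_s)
    anchors <- anchors[anchors - L >= 1 & anchors + L - 1 <= length(target)]
    if (!is.null(valid_mask)) anchors <- anchors[valid_mask[anchors]]
  } else {
    stop("provide anchor_series or event_times_s")
  }
  prsa_average(target, anchors, L)
}

#' Anchor eligibility mask over beats
#'
#' `TRUE` for beats whose +-2-beat neighbourhood is entirely sinus (`N`),
#' so that averaged windows are anchored away from ectopy and artifact.
#'
#' @param labels per-beat labels.
#' @param margin neighbourhood half-width in beats.
#' @return logical vector, one per beat.
#' @export
sinus_anchor_mask <- function(labels, margin = 2L) {
  n <- length(labels)
  bad <- which(labels != "N")
  mask <- rep(TRUE, n)
  for (b in bad) {
    mask[max(1L, b - margin):min(n, b + margin)] <- FALSE
  }
  mask
}
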