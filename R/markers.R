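## The seven Polyscore constituent markers, each returning a MarkerResult
## carrying the continuous value, its dichotomy, and support counts.

marker_result <- function(name, value, units, threshold, abnormal,
                          evaluable, n_support, detail = list()) {
  structure(
    list(
      name = name, value = value, units = units, threshold = threshold,
      abnormal = abnormal, evaluable = evaluable,
      n_support = as.integer(n_support), detail = detail
    ),
    class = "marker_result"
  )
}

#' @export
print.marker_result <- function(x, ...) {
  cat(sprintf(
    "<marker %s> value %s %s | %s | n=%d\n",
    x$name,
    paste(signif(x$value, 4), collapse = "/"),
    x$units,
    if (!x$evaluable) "not evaluable" else if (isTRUE(x$abnormal)) "ABNORMAL" else "normal",
    x$n_support
  ))
  invisible(x)
}

not_evaluable <- function(name, units, threshold, n_support = 0,
                          detail = list()) {
  marker_result(name, NA_real_, units, threshold, NA, FALSE, n_support,
    detail)
}

#' Dichotomize a marker value at its threshold
#'
#' Boundary semantics follow the threshold's `abnormal_side` exactly:
#' `below_or_equal` flags `value <= threshold`, `at_or_above` flags
#' `value >= threshold`, `above` flags strict `value > threshold` (applied
#' element-wise, abnormal when any element exceeds, for paired thresholds
#' like the ectopy counts).
#'
#' @param value numeric marker value (vector for paired thresholds).
#' @param spec a [threshold_spec()].
#' @return `TRUE`/`FALSE`, or `NA` for a non-evaluable (NA) value.
#' @export
dichotomize <- function(value, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  if (any(is.na(value))) return(NA)
  thr <- spec$threshold_value
  switch(spec$abnormal_side,
    below_or_equal = any(value <= thr),
    at_or_above = any(value >= thr),
    above = any(value > thr)
  )
}

## rr interval j (between beats j and j+1) is an eligible anchor position
## when the beats j-2 .. j+3 (clamped) are all sinus, so that the rr values
## at quartet offsets -2..1 are all normal-to-normal intervals. After a
## ventricular ectopic the exclusion extends over the heart-rate-turbulence
## transient (~16 beats), which is a baroreflex response, not the ongoing
## vagal modulation the PRSA markers quantify.
rr_anchor_mask <- function(labels, post_v = 16L) {
  n_rr <- length(labels) - 1L
  if (n_rr < 1) return(logical(0))
  mask <- rep(TRUE, n_rr)
  bad <- which(labels != "N")
  for (b in bad) {
    post <- if (labels[b] == "V") post_v else 2L
    mask[max(1L, b - 3L):min(n_rr, b + post)] <- FALSE
  }
  mask
}

local_pre_vpc_median <- function(rr, v) {
  idx <- (v - 6):(v - 2)
  median(rr[idx])
}

eligible_vpcs <- function(bs, prematurity_frac = 0.8, pause_frac = 1.2,
                          n_pre = 5, n_post = 15) {
  n <- bs$n_beats
  rr <- bs$rr_ms
  labels <- bs$labels
  vs <- which(labels == "V")
  vs <- vs[vs - n_pre - 1 >= 1 & vs + n_post + 1 <= n]
  keep <- vapply(vs, function(v) {
    pre_beats <- labels[(v - n_pre - 1):(v - 1)]
    post_beats <- labels[(v + 1):(v + n_post + 1)]
    if (!all(pre_beats == "N") || !all(post_beats == "N")) return(FALSE)
    med <- local_pre_vpc_median(rr, v)
    coupling <- rr[v - 1]
    pause <- rr[v]
    coupling < prematurity_frac * med && pause > pause_frac * med
  }, logical(1))
  vs[keep]
}

#' Heart rate turbulence slope (TS)
#'
#' Eligible ventricular premature beats (coupling interval < 80% and
#' compensatory pause > 120% of the local sinus median RR, with at least 5
#' sinus intervals before and 15 after) contribute their 15 post-pause sinus
#' RR intervals; these tachograms are averaged across VPCs and TS is the
#' maximum least-squares slope over any 5 consecutive intervals of the
#' average (ties to the earliest window). Abnormal when TS <= 2.5 ms/RR.
#' With no eligible VPC the marker is not evaluable (resolution is left to
#' the Polyscore's no-VPC policy).
#'
#' @param bs a labelled [beat_series()].
#' @param threshold a [threshold_spec()]; default the published 2.5 ms/RR.
#' @return A `marker_result`.
#' @export
compute_turbulence_slope <- function(bs, threshold = default_thresholds()$TS) {
  vpcs <- eligible_vpcs(bs)
  if (!length(vpcs)) {
    return(not_evaluable("TS", "ms/RR", threshold))
  }
  tach <- vapply(vpcs, function(v) bs$rr_ms[(v + 1):(v + 15)], numeric(15))
  avg <- rowMeans(tach)
  x <- 1:5
  slopes <- vapply(1:11, function(w) {
    y <- avg[w:(w + 4)]
    sum((x - 3) * (y - mean(y))) / 10
  }, numeric(1))
  ts <- max(slopes)
  marker_result("TS", ts, "ms/RR", threshold, dichotomize(ts, threshold),
    TRUE, length(vpcs),
    detail = list(averaged_tachogram = avg, window_slopes = slopes,
      vpc_indices = vpcs)
  )
}

#' Deceleration capacity (DC)
#'
#' Quartet measure of univariate phase-rectified signal averaging of the RR
#' series, anchored at RR prolongations (with the configured eligibility
#' ceiling on the relative increase). Abnormal when DC <= 2.5 ms. Fewer
#' than `config$min_anchors` anchors makes the marker not evaluable.
#'
#' @param bs a labelled [beat_series()].
#' @param config a [prsa_config()].
#' @param threshold a [threshold_spec()].
#' @return A `marker_result`.
#' @export
compute_dc <- function(bs, config = prsa_config(),
                       threshold = default_thresholds()$DC) {
  rr <- bs$rr_ms
  mask <- rr_anchor_mask(bs$labels)
  anchors <- select_anchors(rr, "rr_increase", config, valid_mask = mask)
  if (length(anchors) < config$min_anchors) {
    return(not_evaluable("DC", "ms", threshold, length(anchors)))
  }
  pr <- prsa_average(rr, anchors, config$half_window_L)
  dc <- quartet_measure(pr)
  marker_result("DC", dc, "ms", threshold, dichotomize(dc, threshold),
    TRUE, pr$n_anchors, detail = list(prsa = pr)
  )
}

#' Baroreflex sensitivity (BRS) by bivariate PRSA
#'
#' Anchors are systolic-pressure rises; the RR series and the SBP series
#' are phase-rectified-averaged at the same anchors and BRS is the ratio of
#' the two quartet measures, in ms/mmHg. Abnormal when BRS <= 1.58 ms/mmHg.
#' A non-positive SBP quartet (degenerate anchor set) or too few anchors
#' makes the marker not evaluable.
#'
#' @param bs a labelled [beat_series()].
#' @param sbp an [sbp_series()] aligned to the beats.
#' @param config a [prsa_config()].
#' @param threshold a [threshold_spec()].
#' @return A `marker_result`.
#' @export
compute_brs <- function(bs, sbp, config = prsa_config(),
                        threshold = default_thresholds()$BRS) {
  n <- bs$n_beats
  if (n < 3) return(not_evaluable("BRS", "ms/mmHg", threshold))
  rr <- bs$rr_ms # rr[j]: interval between beats j and j+1
  sbp_v <- sbp$values_mmHg
  sbp_v[!sbp$valid_mask] <- NA_real_
  # beat-aligned series over beats 2..n: RR terminating at the beat, SBP at it
  sbp_b <- sbp_v[2:n]
  mask <- rr_anchor_mask(bs$labels)
  # additionally require valid SBP across the quartet offsets
  n_rr <- length(rr)
  sbp_ok <- vapply(seq_len(n_rr), function(j) {
    idx <- (j - 2):(j + 1)
    idx <- idx[idx >= 1 & idx <= n_rr]
    all(is.finite(sbp_b[idx]))
  }, logical(1))
  anchors <- select_anchors(
    ifelse(is.finite(sbp_b), sbp_b, -Inf), "bp_rise", config,
    valid_mask = mask & sbp_ok
  )
  if (length(anchors) < config$min_anchors) {
    return(not_evaluable("BRS", "ms/mmHg", threshold, length(anchors)))
  }
  L <- config$half_window_L
  pr_rr <- prsa_average(rr, anchors, L)
  sbp_filled <- sbp_b
  sbp_filled[!is.finite(sbp_filled)] <- mean(sbp_b, na.rm = TRUE)
  pr_sbp <- prsa_average(sbp_filled, anchors, L)
  q_sbp <- quartet_measure(pr_sbp)
  # a quartet below 0.05 mmHg is not a pressure rise, it is sample-
  # resolution noise on a flat pressure: degenerate anchor set
  if (!is.finite(q_sbp) || q_sbp <= 0.05) {
    return(not_evaluable("BRS", "ms/mmHg", threshold, pr_rr$n_anchors))
  }
  brs <- quartet_measure(pr_rr) / q_sbp
  marker_result("BRS", brs, "ms/mmHg", threshold,
    dichotomize(brs, threshold), TRUE, pr_rr$n_anchors,
    detail = list(quartet_rr = quartet_measure(pr_rr), quartet_sbp = q_sbp)
  )
}

#' Resting respiration rate over the final 10 minutes
#'
#' Breath onsets within the half-open window `[T - 600 s, T)` at the end of
#' the recording, divided by 10, in breaths/min. Abnormal when the rate is
#' >= 18.6 breaths/min. Recordings shorter than 600 s, or windows with
#' fewer than 30 breaths, are not evaluable.
#'
#' @param breaths a [breath_series()].
#' @param recording_duration_s total recording duration in seconds.
#' @param threshold a [threshold_spec()].
#' @return A `marker_result`.
#' @export
compute_respiration_rate <- function(breaths, recording_duration_s,
                                     threshold = default_thresholds()$RESP) {
  if (recording_duration_s < 600) {
    return(not_evaluable("RESP", "breaths/min", threshold))
  }
  t0 <- recording_duration_s - 600
  k <- sum(breaths$breath_onset_times_s >= t0 &
    breaths$breath_onset_times_s < recording_duration_s)
  if (k < 30) {
    return(not_evaluable("RESP", "breaths/min", threshold, k))
  }
  rate <- k / 10
  marker_result("RESP", rate, "breaths/min", threshold,
    dichotomize(rate, threshold), TRUE, k
  )
}

#' Expiration-triggered sinus arrhythmia (ETA)
#'
#' Quartet measure of bivariate PRSA of the RR series anchored at
#' expiration onsets (each mapped to the first beat at or after the onset).
#' Abnormal when ETA <= 0.19 ms. Fewer than `config$min_anchors` mappable
#' anchors makes the marker not evaluable.
#'
#' @param bs a labelled [beat_series()].
#' @param breaths a [breath_series()].
#' @param config a [prsa_config()].
#' @param threshold a [threshold_spec()].
#' @return A `marker_result`.
#' @export
compute_eta <- function(bs, breaths, config = prsa_config(),
                        threshold = default_thresholds()$ETA) {
  if (!length(breaths$expiration_onset_times_s) || bs$n_beats < 3) {
    return(not_evaluable("ETA", "ms", threshold))
  }
  rr <- bs$rr_ms
  beat_idx <- events_to_beat_indices(
    breaths$expiration_onset_times_s, bs$beat_times_s
  )
  anchors <- beat_idx - 1L # rr index of the interval terminating at the beat
  L <- config$half_window_L
  anchors <- anchors[anchors - L >= 1 & anchors + L - 1 <= length(rr)]
  mask <- rr_anchor_mask(bs$labels)
  anchors <- anchors[mask[anchors]]
  if (length(anchors) < config$min_anchors) {
    return(not_evaluable("ETA", "ms", threshold, length(anchors)))
  }
  pr <- prsa_average(rr, anchors, L)
  eta <- quartet_measure(pr)
  marker_result("ETA", eta, "ms", threshold, dichotomize(eta, threshold),
    TRUE, pr$n_anchors, detail = list(prsa = pr)
  )
}

#' Post-ectopic potentiation of systolic blood pressure (PESP)
#'
#' For each eligible ventricular premature beat, the ratio of the systolic
#' pressure of the first post-ectopic sinus beat to the mean systolic
#' pressure of the following five sinus cycles (beats 2-6 after the VPC);
#' the marker value is the mean ratio across eligible VPCs. PESP is present
#' (abnormal) when the ratio is >= 1.03. No eligible VPC with valid
#' pressures makes the marker not evaluable (resolved by the no-VPC
#' policy).
#'
#' @param bs a labelled [beat_series()].
#' @param sbp an [sbp_series()] aligned to the beats.
#' @param threshold a [threshold_spec()].
#' @return A `marker_result`.
#' @export
compute_pesp <- function(bs, sbp, threshold = default_thresholds()$PESP) {
  n <- bs$n_beats
  rr <- bs$rr_ms
  labels <- bs$labels
  sbp_v <- sbp$values_mmHg
  sbp_v[!sbp$valid_mask] <- NA_real_
  vs <- which(labels == "V")
  vs <- vs[vs - 6 >= 1 & vs + 6 <= n]
  ratios <- c()
  used <- integer(0)
  for (v in vs) {
    med <- local_pre_vpc_median(rr, v)
    if (!is.finite(med)) next
    if (!(rr[v - 1] < 0.8 * med && rr[v] > 1.2 * med)) next
    post <- (v + 1):(v + 6)
    if (!all(labels[post] == "N")) next
    s1 <- sbp_v[v + 1]
    rest <- sbp_v[(v + 2):(v + 6)]
    if (!is.finite(s1) || !all(is.finite(rest))) next
    ratios <- c(ratios, s1 / mean(rest))
    used <- c(used, v)
  }
  if (!length(ratios)) {
    return(not_evaluable("PESP", "ratio", threshold))
  }
  val <- mean(ratios)
  marker_result("PESP", val, "ratio", threshold, dichotomize(val, threshold),
    TRUE, length(ratios),
    detail = list(per_vpc_ratios = ratios, vpc_indices = used)
  )
}

#' Ectopy frequency per 30 minutes
#'
#' Counts of supraventricular (`S`) and ventricular (`V`) ectopic beats,
#' scaled to a 30-minute equivalent (`count * 1800 / duration_s`). Abnormal
#' when SVE count > 7 or VE count > 29 per 30 min (strict inequalities).
#'
#' @param bs a labelled [beat_series()].
#' @param duration_s recording duration in seconds.
#' @param threshold a [threshold_spec()] with paired `c(sve, ve)` limits.
#' @return A `marker_result` whose value is the named pair of scaled counts.
#' @export
compute_ectopy <- function(bs, duration_s,
                           threshold = default_thresholds()$ECTOPY) {
  scale <- 1800 / duration_s
  val <- c(
    sve = sum(bs$labels == "S") * scale,
    ve = sum(bs$labels == "V") * scale
  )
  marker_result("ECTOPY", val, "count/30min", threshold,
    dichotomize(val, threshold), TRUE,
    sum(bs$labels %in% c("S", "V"))
  )
}

#' Compute all seven Polyscore markers
#'
#' @param bs labelled [beat_series()].
#' @param sbp [sbp_series()] aligned to the beats.
#' @param breaths [breath_series()].
#' @param duration_s recording duration (s).
#' @param config [prsa_config()].
#' @param thresholds named list of [threshold_spec()]s, see
#'   [default_thresholds()].
#' @return Named list of seven `marker_result`s, in Polyscore order
#'   (TS, DC, BRS, RESP, ETA, PESP, ECTOPY).
#' @export
compute_markers <- function(bs, sbp, breaths, duration_s,
                            config = prsa_config(),
                            thresholds = default_thresholds()) {
  list(
    TS = compute_turbulence_slope(bs, thresholds$TS),
    DC = compute_dc(bs, config, thresholds$DC),
    BRS = compute_brs(bs, sbp, config, thresholds$BRS),
    RESP = compute_respiration_rate(breaths, duration_s, thresholds$RESP),
    ETA = compute_eta(bs, breaths, config, thresholds$ETA),
    PESP = compute_pesp(bs, sbp, thresholds$PESP),
    ECTOPY = compute_ectopy(bs, duration_s, thresholds$ECTOPY)
  )
}

#' Tabulate marker results
#'
#' One row per marker: name, value (formatted), units, threshold, abnormal
#' side, abnormal flag, evaluability and support count.
#'
#' @param markers named list of `marker_result`s.
#' @return data.frame.
#' @export
marker_report <- function(markers) {
  do.call(rbind, lapply(markers, function(m) {
    data.frame(
      name = m$name,
      value = paste(signif(m$value, 6), collapse = ";"),
      units = m$units,
      threshold = paste(m$threshold$threshold_value, collapse = ";"),
      abnormal_side = m$threshold$abnormal_side,
      abnormal = m$abnormal,
      evaluable = m$evaluable,
      n_support = m$n_support,
      stringsAsFactors = FALSE
    )
  }))
}
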