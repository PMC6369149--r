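## Automated beat detection and labelling: R peaks, QRS widths, beat
## classification (N/V/S/X), artifact filtering, per-beat systolic
## pressures, breath detection. Replaces manual technician review with
## explicit, deterministic rules.

butter_filtfilt <- function(x, fs, low, high, order = 2) {
  w <- c(low, high) / (fs / 2)
  w <- pmin(pmax(w, 1e-6), 0.999)
  bf <- signal::butter(order, w, type = "pass")
  signal::filtfilt(bf, x)
}

#' Detect R peaks in a single ECG channel
#'
#' Pan-Tompkins-style detector: band-pass 5-30 Hz, squared derivative,
#' 150 ms moving-window integration, adaptive threshold (a fraction of the
#' median of per-segment maxima), and a 200 ms refractory period. Peak times
#' are refined to the maximum of the absolute band-passed ECG near each
#' integrated-energy peak.
#'
#' @param ecg_channel numeric ECG samples (mV).
#' @param fs sampling frequency in Hz (must be >= 100).
#' @param threshold_frac fraction of the robust signal maximum used as
#'   detection threshold.
#' @return numeric vector of strictly increasing R-peak times in seconds.
#'   A flat or empty signal yields `numeric(0)` with a warning.
#' @export
detect_r_peaks <- function(ecg_channel, fs, threshold_frac = 0.35) {
  if (fs < 100) stop("detect_r_peaks needs fs >= 100 Hz")
  n <- length(ecg_channel)
  if (n < 10 * fs) stop("detect_r_peaks needs at least 10 s of signal")
  if (!any(is.finite(ecg_channel)) || sd(ecg_channel, na.rm = TRUE) < 1e-12) {
    warning("flat ECG signal: no beats detected")
    return(numeric(0))
  }
  bp <- butter_filtfilt(ecg_channel, fs, 5, 30)
  energy <- c(0, diff(bp))^2
  win <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(energy, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0
  # robust amplitude reference: median of maxima over ~10 equal segments
  nseg <- 10L
  seg <- pmin(ceiling(seq_len(n) / (n / nseg)), nseg)
  ref <- median(tapply(integ, seg, max))
  if (!is.finite(ref) || ref <= 0) {
    warning("no QRS energy found: no beats detected")
    return(numeric(0))
  }
  thr <- threshold_frac * ref
  above <- integ > thr
  # candidate peaks: local maxima of the integrated energy above threshold
  cand <- which(above &
    integ >= c(-Inf, integ[-n]) & integ > c(integ[-1], -Inf))
  if (!length(cand)) {
    warning("no peaks above threshold: no beats detected")
    return(numeric(0))
  }
  refr <- round(0.2 * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last > refr) {
      keep <- c(keep, i)
      last <- i
    } else if (integ[i] > integ[last]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  # refine to the |band-passed| maximum within +-100 ms
  half <- round(0.1 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    lo + which.max(abs(bp[lo:hi])) - 1
  }, numeric(1))
  peaks <- sort(unique(peaks))
  # enforce refractory after refinement
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if ((p - out[length(out)]) > refr) out <- c(out, p)
    }
    peaks <- out
  }
  (peaks - 1) / fs
}

#' Estimate QRS widths at detected beats
#'
#' Truncated-moment width: within a +-150 ms window around each R peak,
#' only samples whose baseline-corrected amplitude exceeds 20% of the peak
#' contribute; the amplitude-weighted second moment of time about the peak
#' gives a Gaussian-equivalent sigma (rescaled analytically for the 20%
#' truncation), and width is reported as 6 sigma, the full support of a
#' Gaussian-like complex, in ms. The truncation makes the estimate immune
#' to low-level baseline noise.
#'
#' @param ecg_channel numeric ECG samples.
#' @param fs sampling frequency (Hz).
#' @param beat_times_s R-peak times from [detect_r_peaks()].
#' @return numeric vector of widths in ms, one per beat.
#' @export
measure_qrs_widths <- function(ecg_channel, fs, beat_times_s) {
  n <- length(ecg_channel)
  half <- round(0.15 * fs)
  base <- median(ecg_channel, na.rm = TRUE)
  # second moment of a Gaussian truncated at 20% of its peak (|t| <= t0):
  # sigma_hat^2 = c2 * sigma^2, correct back by 1/sqrt(c2)
  t0 <- sqrt(2 * log(5))
  c2 <- 1 - 2 * t0 * stats::dnorm(t0) / (2 * stats::pnorm(t0) - 1)
  vapply(beat_times_s, function(t) {
    i <- round(t * fs) + 1
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    w <- abs(ecg_channel[lo:hi] - base)
    keep <- w >= 0.2 * max(w)
    if (!any(keep) || sum(w[keep]) <= 0) return(NA_real_)
    tt <- ((lo:hi) - i) / fs
    sigma <- sqrt(sum(w[keep] * tt[keep]^2) / sum(w[keep]) / c2)
    6000 * sigma
  }, numeric(1))
}

local_sinus_median_rr <- function(rr, labels_of_rr, i, half_window = 5L) {
  ## median of nearby sinus (NN) RRs, excluding interval i itself
  n <- length(rr)
  lo <- max(1L, i - half_window)
  hi <- min(n, i + half_window)
  idx <- setdiff(lo:hi, i)
  idx <- idx[labels_of_rr[idx]]
  if (!length(idx)) idx <- setdiff(lo:hi, i)
  if (!length(idx)) return(NA_real_)
  median(rr[idx])
}

#' Classify beats as sinus, ventricular, supraventricular or artifact
#'
#' Rule-based labelling of a detected beat series. A beat is *premature*
#' when its coupling interval is < 80% of the local median sinus RR
#' (median over the surrounding +-5 NN intervals). A premature beat is
#' labelled `V` when its QRS is wide (> `qrs_wide_ms`, default 120 ms) or
#' its pause is compensatory (coupling + pause within +-10% of twice the
#' local median RR); `S` when narrow with a non-compensatory (resetting)
#' pause; beats violating RR plausibility (RR < 300 ms or > 2000 ms) are
#' labelled `X`. Everything else stays `N`.
#'
#' @param bs a [beat_series()] (labels are recomputed; existing `X` labels
#'   are preserved).
#' @param qrs_width_ms per-beat QRS widths in ms (from
#'   [measure_qrs_widths()]); `NA` widths disable the width criterion for
#'   that beat.
#' @param qrs_wide_ms width threshold separating wide from narrow complexes.
#' @param prematurity_frac coupling-interval fraction below which a beat is
#'   premature.
#' @param compensatory_tol relative tolerance on "coupling + pause = 2 x RR".
#' @return A [beat_series()] with updated labels.
#' @export
classify_beats <- function(bs, qrs_width_ms = NULL, qrs_wide_ms = 120,
                           prematurity_frac = 0.8, compensatory_tol = 0.1) {
  stopifnot(inherits(bs, "beat_series"))
  n <- bs$n_beats
  if (n < 20) {
    warning("fewer than 20 beats: all labelled X (no reference rhythm)")
    return(beat_series(bs$beat_times_s, rep("X", n)))
  }
  if (is.null(qrs_width_ms)) qrs_width_ms <- rep(NA_real_, n)
  rr <- bs$rr_ms
  labels <- bs$labels
  nn <- rep(TRUE, n - 1) # provisional: treat all RRs as usable for medians
  for (i in 2:n) {
    if (labels[i] == "X") next
    ci <- rr[i - 1] # coupling interval terminating at beat i
    if (ci < 300 || ci > 2000) {
      labels[i] <- "X"
      next
    }
    med <- local_sinus_median_rr(rr, nn, i - 1)
    if (!is.finite(med)) next
    premature <- ci < prematurity_frac * med
    if (!premature) next
    pause <- if (i <= n - 1) rr[i] else NA_real_
    compensatory <- is.finite(pause) &&
      abs((ci + pause) - 2 * med) <= compensatory_tol * 2 * med
    wide <- is.finite(qrs_width_ms[i]) && qrs_width_ms[i] > qrs_wide_ms
    if (wide || compensatory) {
      labels[i] <- "V"
    } else {
      labels[i] <- "S"
    }
    nn[i - 1] <- FALSE
    if (i <= n - 1) nn[i] <- FALSE
  }
  beat_series(bs$beat_times_s, labels)
}

#' Relabel artifact beats by RR plausibility rules
#'
#' Two rules, applied to beats currently labelled `N`: (a) an RR interval
#' outside 300-2000 ms marks the terminating beat `X`; (b) a normal-to-normal
#' interval deviating more than 25% from the running median of the last 5
#' accepted sinus RRs marks the terminating beat `X`. The jump rule is
#' restricted to NN intervals (both endpoints labelled `N`): coupling
#' intervals and compensatory pauses of recognized ectopic beats are
#' physiology, not artifact. Beat times are never altered.
#'
#' @param bs a [beat_series()] with labels (typically from
#'   [classify_beats()]).
#' @param jump_frac relative deviation against the running median that
#'   triggers the artifact rule.
#' @return A [beat_series()] with artifact beats relabelled `X`.
#' @export
filter_artifacts <- function(bs, jump_frac = 0.25) {
  stopifnot(inherits(bs, "beat_series"))
  n <- bs$n_beats
  if (n < 2) return(bs)
  rr <- bs$rr_ms
  labels <- bs$labels
  recent <- numeric(0) # running store of accepted sinus RRs
  for (i in 2:n) {
    ci <- rr[i - 1]
    if (labels[i] == "N" && (ci < 300 || ci > 2000)) {
      labels[i] <- "X"
      next
    }
    if (labels[i] != "N" || labels[i - 1] != "N") next
    if (length(recent) >= 5) {
      med <- median(tail(recent, 5))
      if (abs(ci - med) > jump_frac * med) {
        labels[i] <- "X"
        next
      }
    }
    recent <- c(tail(recent, 9), ci)
  }
  beat_series(bs$beat_times_s, labels)
}

#' Extract per-beat systolic pressures from the pressure waveform
#'
#' For each beat the systolic pressure is the maximum of the arterial
#' pressure waveform in the window from the R peak to half of the following
#' RR interval. Beats whose window extends past the end of the signal (or
#' the final beat, which has no following RR) are marked invalid; values
#' outside the 50-250 mmHg plausibility window are flagged invalid but kept,
#' preserving beat alignment.
#'
#' @param bp_waveform arterial pressure samples (mmHg).
#' @param beat_times_s R-peak times (s).
#' @param fs sampling frequency (Hz).
#' @return An [sbp_series()] aligned to the beats.
#' @export
extract_systolic_pressures <- function(bp_waveform, beat_times_s, fs) {
  n <- length(bp_waveform)
  nb <- length(beat_times_s)
  values <- rep(NA_real_, nb)
  valid <- rep(FALSE, nb)
  if (nb >= 2) {
    for (i in seq_len(nb - 1)) {
      t0 <- beat_times_s[i]
      t1 <- t0 + 0.5 * (beat_times_s[i + 1] - t0)
      i0 <- floor(t0 * fs) + 1
      i1 <- floor(t1 * fs) + 1
      if (i1 > n) next # window beyond signal end
      values[i] <- max(bp_waveform[i0:i1])
      valid[i] <- TRUE
    }
  }
  out <- sbp_series(values, seq_len(nb))
  out$valid_mask <- out$valid_mask & valid
  out
}

#' Detect breaths in the respiration signal
#'
#' The respiration channel is decimated to ~8 Hz (with moving-average
#' anti-aliasing), band-passed to 0.05-1 Hz, and breath onsets taken as
#' upward zero crossings (linearly interpolated); expiration onsets are the
#' signal maxima between consecutive breath onsets (end-inspiration).
#' When no quasi-regular oscillation is present (fewer than 2 crossings, or
#' a breath-interval coefficient of variation above 0.35), an empty series
#' is returned with a warning.
#'
#' @param resp_waveform respiration samples (arbitrary units).
#' @param fs sampling frequency (Hz).
#' @return A [breath_series()].
#' @export
detect_breaths <- function(resp_waveform, fs) {
  n <- length(resp_waveform)
  if (n < 60 * fs) stop("detect_breaths needs at least 60 s of signal")
  dec <- max(1L, floor(fs / 8))
  if (dec > 1) {
    sm <- as.numeric(stats::filter(resp_waveform, rep(1 / dec, dec), sides = 2))
    sm[is.na(sm)] <- resp_waveform[is.na(sm)]
    x <- sm[seq(1L, n, by = dec)]
  } else {
    x <- resp_waveform
  }
  fs_d <- fs / dec
  if (sd(x) < 1e-12) {
    warning("flat respiration signal: no breaths detected")
    return(breath_series(numeric(0), numeric(0)))
  }
  xf <- butter_filtfilt(x, fs_d, 0.05, 1)
  m <- length(xf)
  up <- which(xf[-m] < 0 & xf[-1] >= 0)
  if (length(up) < 2) {
    warning("no respiratory oscillation detected")
    return(breath_series(numeric(0), numeric(0)))
  }
  # linear interpolation of the crossing instant
  frac <- -xf[up] / (xf[up + 1] - xf[up])
  onset_t <- (up - 1 + frac) / fs_d
  iv <- diff(onset_t)
  # resting breathing is quasi-periodic (interval CV well under 0.2);
  # crossings of band-passed noise run a CV near 0.5
  if (sd(iv) / mean(iv) > 0.35) {
    warning("respiration oscillation too irregular: treated as absent")
    return(breath_series(numeric(0), numeric(0)))
  }
  exp_t <- vapply(seq_len(length(up) - 1), function(k) {
    seg <- up[k]:up[k + 1]
    (seg[which.max(xf[seg])] - 1) / fs_d
  }, numeric(1))
  breath_series(onset_t, exp_t)
}

#' Detect and label beats from a recording
#'
#' Convenience chain: R-peak detection on the X lead (falling back to the
#' ECG vector magnitude when the detected rate is outside 30-150 beats/min),
#' QRS width measurement, beat classification, then artifact filtering.
#'
#' @param rec a [recording()].
#' @param ... passed to [classify_beats()].
#' @return A labelled, artifact-filtered [beat_series()].
#' @export
detect_beats <- function(rec, ...) {
  lead <- rec$ecg[, 1]
  times <- detect_r_peaks(lead, rec$fs)
  rate <- length(times) / rec$duration_s * 60
  if ((rate < 30 || rate > 150) && ncol(rec$ecg) > 1) {
    lead <- sqrt(rowSums(rec$ecg^2))
    times <- detect_r_peaks(lead, rec$fs)
  }
  if (!length(times)) {
    return(beat_series(numeric(0), character(0)))
  }
  widths <- measure_qrs_widths(lead, rec$fs, times)
  bs <- beat_series(times)
  bs <- classify_beats(bs, qrs_width_ms = widths, ...)
  filter_artifacts(bs)
}
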