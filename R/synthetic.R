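## Synthetic physiology: 30-min recordings with known ground-truth marker
## values (RSA-modulated tachograms, injected ectopics with programmed
## turbulence, pressure series coupled to RR through a configurable
## baroreflex gain and post-ectopic potentiation), and cohorts with known
## per-stratum exponential hazards.

#' Ground-truth physiological profile for the recording generator
#'
#' Defaults emulate a supine resting 30-min recording of a beta-blocked
#' post-infarction patient with preserved autonomic function: mean RR
#' 900 ms, respiratory sinus arrhythmia 15 ms at 15 breaths/min, baroreflex
#' gain 8 ms/mmHg, 10 isolated ventricular ectopics with turbulence slope
#' 8 ms/beat, no supraventricular ectopy, no post-ectopic potentiation,
#' systolic pressure 120 mmHg with a 5 mmHg low-frequency (9.3 s Mayer-wave)
#' oscillation. All seven markers land on their normal side, so the default
#' profile analyzes to Polyscore 0.
#'
#' @param mean_rr_ms mean sinus RR interval (ms).
#' @param rsa_amplitude_ms respiratory sinus arrhythmia amplitude (ms).
#' @param resp_rate_bpm respiration rate (breaths/min).
#' @param brs_gain_ms_per_mmHg baroreflex gain coupling RR to systolic
#'   pressure deviations (ms/mmHg).
#' @param n_vpc,n_sve numbers of injected ventricular / supraventricular
#'   ectopics over the recording.
#' @param turbulence_slope_ms_per_beat programmed post-VPC turbulence slope.
#' @param pesp_fraction relative systolic overshoot of the first
#'   post-ectopic beat (0.08 = +8%).
#' @param sbp_mean_mmHg,sbp_lf_oscillation_mmHg,lf_period_s systolic
#'   pressure mean, low-frequency oscillation amplitude and period.
#' @param rr_jitter_ms white RR jitter SD (ms).
#' @param rr_drift_ms,drift_period_s slow RR drift amplitude and period.
#' @param sbp_noise_mmHg white per-beat systolic pressure noise SD.
#' @param ecg_noise_mv,resp_noise additive waveform noise SDs.
#' @param resp_phase0 initial respiration phase (rad); kept away from 0 so
#'   breath onsets do not coincide with window boundaries.
#' @param duration_s recording duration (s).
#' @param fs rendering sample rate (Hz).
#' @param seed RNG seed.
#' @return list of class `physio_profile`.
#' @export
physio_profile <- function(mean_rr_ms = 900, rsa_amplitude_ms = 15,
                           resp_rate_bpm = 15, brs_gain_ms_per_mmHg = 8,
                           n_vpc = 10, n_sve = 0,
                           turbulence_slope_ms_per_beat = 8,
                           pesp_fraction = 0, sbp_mean_mmHg = 120,
                           sbp_lf_oscillation_mmHg = 5, lf_period_s = 9.3,
                           rr_jitter_ms = 2, rr_drift_ms = 10,
                           drift_period_s = 300, sbp_noise_mmHg = 1,
                           ecg_noise_mv = 0.01, resp_noise = 0.02,
                           resp_phase0 = 1, duration_s = 1800, fs = 250,
                           seed = 1L) {
  stopifnot(
    mean_rr_ms >= 300, mean_rr_ms <= 2000,
    rsa_amplitude_ms >= 0, resp_rate_bpm > 0, brs_gain_ms_per_mmHg >= 0,
    n_vpc >= 0, n_sve >= 0, pesp_fraction >= -0.5, duration_s > 0, fs > 0
  )
  structure(as.list(environment()), class = "physio_profile")
}

#' Generate an RR tachogram with respiratory sinus arrhythmia
#'
#' Beat-by-beat construction: each RR interval is the profile mean plus an
#' RSA term phase-locked to the respiration oscillator (RR lengthening
#' during early expiration), a slow sinusoidal drift, and white jitter.
#' Beat times accumulate from the RR sequence.
#'
#' @param profile a [physio_profile()].
#' @param seed RNG seed; `NULL` keeps the current RNG state (used when an
#'   orchestrator has already seeded).
#' @return list with `rr_ms`, `beat_times_s` (one more element than
#'   `rr_ms`), and `resp_freq_hz`.
#' @export
generate_tachogram <- function(profile, seed = profile$seed) {
  if (!is.null(seed)) set.seed(seed)
  f <- profile$resp_rate_bpm / 60
  t <- 0.5
  times <- t
  rr <- numeric(0)
  rsa <- numeric(0)
  repeat {
    # RSA evaluated at the interval's end: the interval terminating at a
    # beat reflects the autonomic state when that beat fires
    t_end <- t + profile$mean_rr_ms / 1000
    r <- -profile$rsa_amplitude_ms *
      cos(2 * pi * f * t_end + profile$resp_phase0)
    x <- profile$mean_rr_ms + r +
      profile$rr_drift_ms * sin(2 * pi * t / profile$drift_period_s) +
      rnorm(1, 0, profile$rr_jitter_ms)
    x <- max(x, 300)
    t_next <- t + x / 1000
    if (t_next > profile$duration_s - 0.5) break
    rr <- c(rr, x)
    rsa <- c(rsa, r)
    times <- c(times, t_next)
    t <- t_next
  }
  list(rr_ms = rr, beat_times_s = times, resp_freq_hz = f,
    rsa_component_ms = rsa)
}

## Post-VPC turbulence pattern: 15 RR offsets (ms) relative to the sinus
## mean; brief shortening, then a linear deceleration whose maximum 5-beat
## least-squares slope equals `slope` exactly, then linear decay back.
turbulence_pattern <- function(slope, dip = 10) {
  p <- numeric(15)
  p[1:2] <- -dip
  p[3:10] <- -dip + slope * (1:8)
  p[11:15] <- p[10] * (4:0) / 5
  p
}

#' Inject ventricular and supraventricular ectopics into a tachogram
#'
#' VPCs replace a sinus beat with a premature beat at 60% coupling and a
#' compensatory pause completing twice the sinus RR, followed by a 15-beat
#' programmed turbulence response whose maximum 5-beat regression slope
#' equals `turbulence_slope_ms_per_beat` (white jitter is retained inside
#' the response window; RSA/baroreflex modulation is suppressed there so
#' the transient dominates, mirroring the physiological precedence of the
#' post-ectopic baroreflex response). SVEs are premature narrow beats at
#' 55% coupling with a resetting (non-compensatory) pause. Injection sites
#' are block-stratified over the recording, at least 20 sinus beats apart.
#'
#' @param tach list from [generate_tachogram()] (fields `rr_ms`,
#'   `beat_times_s`), or a bare numeric `rr_ms` vector.
#' @param profile a [physio_profile()].
#' @param seed RNG seed (`NULL` = inherit state).
#' @return list: `rr_ms`, `labels` (per beat), `protected` (per RR
#'   interval: inside an ectopic/turbulence window, exempt from later
#'   modulation), `vpc_beats`, `sve_beats`.
#' @export
inject_ectopics <- function(tach, profile, seed = profile$seed) {
  if (!is.null(seed)) set.seed(seed)
  rr <- if (is.list(tach)) tach$rr_ms else as.numeric(tach)
  rsa <- if (is.list(tach) && !is.null(tach$rsa_component_ms)) {
    tach$rsa_component_ms
  } else {
    numeric(length(rr))
  }
  m <- length(rr)
  n_beats <- m + 1
  labels <- rep("N", n_beats)
  protected <- rep(FALSE, m)
  n_ect <- profile$n_vpc + profile$n_sve
  if (n_ect == 0) {
    return(list(rr_ms = rr, labels = labels, protected = protected,
      rsa_component_ms = rsa, resp_freq_hz = tach$resp_freq_hz,
      vpc_beats = integer(0), sve_beats = integer(0)))
  }
  margin <- 25L
  lo <- margin
  hi <- m - margin
  if (hi - lo < n_ect * 45L) {
    stop(sprintf(
      "cannot place %d ectopics in %d beats with >= 20 sinus beats between",
      n_ect, n_beats
    ))
  }
  block <- (hi - lo) / n_ect
  starts <- floor(lo + (seq_len(n_ect) - 1) * block +
    runif(n_ect, 5, block - 40))
  kind <- sample(c(rep("V", profile$n_vpc), rep("S", profile$n_sve)))
  base <- profile$mean_rr_ms
  vpc_beats <- integer(0)
  sve_beats <- integer(0)
  for (k in seq_len(n_ect)) {
    j <- starts[k] # coupling-interval index; ectopic beat is j + 1
    if (kind[k] == "V") {
      rr[j] <- 0.6 * base
      rr[j + 1] <- 2 * base - rr[j]
      pat <- turbulence_pattern(profile$turbulence_slope_ms_per_beat)
      rr[(j + 2):(j + 16)] <- base + pat +
        rnorm(15, 0, profile$rr_jitter_ms)
      labels[j + 1] <- "V"
      protected[j:(j + 16)] <- TRUE
      vpc_beats <- c(vpc_beats, j + 1L)
    } else {
      rr[j] <- 0.55 * base
      rr[j + 1] <- base
      labels[j + 1] <- "S"
      protected[j:(j + 1)] <- TRUE
      sve_beats <- c(sve_beats, j + 1L)
    }
  }
  rsa[protected] <- 0 # replaced intervals no longer carry the RSA term
  list(rr_ms = rr, labels = labels, protected = protected,
    rsa_component_ms = rsa, resp_freq_hz = tach$resp_freq_hz,
    vpc_beats = vpc_beats, sve_beats = sve_beats)
}

#' Generate per-beat systolic pressures coupled to the tachogram
#'
#' Systolic pressure carries a low-frequency (Mayer-wave) oscillation plus
#' white noise; the ectopic beat's own pulse is attenuated (weak ectopic
#' stroke volume) and the first post-ectopic sinus pressure is multiplied
#' by `1 + pesp_fraction`. The baroreflex coupling then adds
#' `gain * (SBP - mean SBP)` to each unprotected sinus RR interval (RR
#' tracking pressure level), which makes the bivariate-PRSA quartet ratio
#' equal the programmed gain by construction.
#'
#' @param ect list from [inject_ectopics()].
#' @param profile a [physio_profile()].
#' @param seed RNG seed (`NULL` = inherit state).
#' @return list: `rr_ms` (baroreflex-coupled), `beat_times_s` (recomputed),
#'   `labels`, `sbp_mmHg` (per beat), `protected`.
#' @export
generate_coupled_bp <- function(ect, profile, seed = profile$seed) {
  if (!is.null(seed)) set.seed(seed)
  rr <- ect$rr_ms
  labels <- ect$labels
  n_beats <- length(rr) + 1
  times <- 0.5 + c(0, cumsum(rr)) / 1000
  lf_phase <- runif(1, 0, 2 * pi)
  sbp <- profile$sbp_mean_mmHg +
    profile$sbp_lf_oscillation_mmHg *
      sin(2 * pi * times / profile$lf_period_s + lf_phase) +
    rnorm(n_beats, 0, profile$sbp_noise_mmHg)
  ectopic <- labels %in% c("V", "S")
  sbp[ectopic] <- sbp[ectopic] * 0.75
  post_vpc <- ect$vpc_beats + 1L
  post_vpc <- post_vpc[post_vpc <= n_beats]
  sbp[post_vpc] <- sbp[post_vpc] * (1 + profile$pesp_fraction)
  j <- seq_along(rr)
  couple <- !ect$protected & labels[j] == "N" & labels[j + 1] == "N"
  # baroreflex: RR terminating at beat i responds to that beat's pressure
  g <- profile$brs_gain_ms_per_mmHg
  if (g > 0) {
    dev <- sbp - profile$sbp_mean_mmHg
    rr[couple] <- rr[couple] + g * dev[j + 1][couple]
  }
  # re-phase the RSA term to the shifted beat times, so the tachogram stays
  # phase-locked to the respiration oscillator after the couplings above
  # have moved the beats
  rsa <- ect$rsa_component_ms
  if (!is.null(rsa) && any(rsa != 0) || profile$rsa_amplitude_ms > 0) {
    rr0 <- rr - rsa
    t_end <- 0.5 + cumsum(rr0) / 1000
    f <- profile$resp_rate_bpm / 60
    rsa_new <- -profile$rsa_amplitude_ms *
      cos(2 * pi * f * t_end + profile$resp_phase0)
    rsa_new[!couple] <- 0
    rr <- rr0 + rsa_new
  }
  times <- 0.5 + c(0, cumsum(rr)) / 1000
  list(rr_ms = rr, beat_times_s = times, labels = labels,
    sbp_mmHg = sbp, protected = ect$protected)
}

gaussian_pulse_train <- function(n, fs, centers_s, amplitudes, sigmas_s) {
  x <- numeric(n)
  for (k in seq_along(centers_s)) {
    c_i <- centers_s[k] * fs + 1
    s_i <- sigmas_s[k] * fs
    lo <- max(1L, floor(c_i - 5 * s_i))
    hi <- min(n, ceiling(c_i + 5 * s_i))
    if (lo > hi) next
    idx <- lo:hi
    x[idx] <- x[idx] + amplitudes[k] * exp(-((idx - c_i)^2) / (2 * s_i^2))
  }
  x
}

#' Synthesize a complete recording with ground truth
#'
#' Chains [generate_tachogram()], [inject_ectopics()] and
#' [generate_coupled_bp()], then renders waveforms at `profile$fs`:
#' ECG as Gaussian QRS templates at the beat times (90 ms support for
#' sinus/supraventricular beats, 140 ms for ventricular, on orthogonal
#' X/Y/Z leads with amplitudes 1.2/0.7/0.5 mV), arterial pressure as
#' Gaussian systolic pulses peaking 150 ms after each R wave at the
#' programmed per-beat systolic value over a 75 mmHg diastolic baseline,
#' and respiration as a unit sinusoid at the profile rate. Fully
#' reproducible from the profile seed.
#'
#' @param profile a [physio_profile()].
#' @return list: `recording` (a [recording()]) and `ground_truth` (beat
#'   times, labels, RR, per-beat SBP, programmed marker values and the
#'   marker flags they imply).
#' @export
synthesize_recording <- function(profile = physio_profile()) {
  set.seed(profile$seed)
  tach <- generate_tachogram(profile, seed = NULL)
  ect <- inject_ectopics(tach, profile, seed = NULL)
  phys <- generate_coupled_bp(ect, profile, seed = NULL)
  fs <- profile$fs
  n <- round(profile$duration_s * fs)
  times <- phys$beat_times_s
  keep <- times < (n - 1) / fs - 0.3
  times <- times[keep]
  labels <- phys$labels[keep]
  sbp <- phys$sbp_mmHg[keep]
  widths <- ifelse(labels == "V", 0.140, 0.090)
  amp <- ifelse(labels == "V", 1.5, 1.2)
  ecg_x <- gaussian_pulse_train(n, fs, times, amp, widths / 6) +
    rnorm(n, 0, profile$ecg_noise_mv)
  ecg_y <- gaussian_pulse_train(n, fs, times, amp * 0.58, widths / 6) +
    rnorm(n, 0, profile$ecg_noise_mv)
  ecg_z <- gaussian_pulse_train(n, fs, times, amp * 0.42, widths / 6) +
    rnorm(n, 0, profile$ecg_noise_mv)
  bp <- 75 + gaussian_pulse_train(n, fs, times + 0.15, sbp - 75,
    rep(0.04, length(times)))
  tt <- (seq_len(n) - 1) / fs
  resp <- sin(2 * pi * tach$resp_freq_hz * tt + profile$resp_phase0) +
    rnorm(n, 0, profile$resp_noise)
  rec <- recording(
    ecg = cbind(X = ecg_x, Y = ecg_y, Z = ecg_z), bp = bp, resp = resp,
    fs = fs, subject_id = sprintf("synthetic-%d", profile$seed)
  )
  thr <- default_thresholds()
  scale30 <- 1800 / profile$duration_s
  truth <- list(
    beat_times_s = times, labels = labels,
    rr_ms = diff(times) * 1000, sbp_mmHg = sbp,
    ts = if (profile$n_vpc > 0) profile$turbulence_slope_ms_per_beat else NA,
    brs = profile$brs_gain_ms_per_mmHg,
    resp_rate = profile$resp_rate_bpm,
    pesp_ratio = 1 + profile$pesp_fraction,
    rsa_amplitude = profile$rsa_amplitude_ms,
    sve_per_30min = profile$n_sve * scale30,
    ve_per_30min = profile$n_vpc * scale30,
    expected_flags = c(
      TS = if (profile$n_vpc > 0) {
        profile$turbulence_slope_ms_per_beat <= thr$TS$threshold_value
      } else FALSE,
      DC = NA, # emergent from RSA/jitter, no closed-form programmed value
      BRS = profile$brs_gain_ms_per_mmHg <= thr$BRS$threshold_value,
      RESP = profile$resp_rate_bpm >= thr$RESP$threshold_value,
      ETA = NA, # emergent; large RSA implies normal, near-zero abnormal
      PESP = if (profile$n_vpc > 0) {
        (1 + profile$pesp_fraction) >= thr$PESP$threshold_value
      } else FALSE,
      ECTOPY = profile$n_sve * scale30 > thr$ECTOPY$threshold_value["sve"] ||
        profile$n_vpc * scale30 > thr$ECTOPY$threshold_value["ve"]
    )
  )
  list(recording = rec, ground_truth = truth)
}

#' Specification of a synthetic survival cohort
#'
#' Defaults mirror the validation population: 941 subjects, stratum
#' membership probabilities proportional to the observed Polyscore strata
#' (239, 261, 182, 133, 86, 24, 9, 7 of 941), per-stratum constant
#' (exponential) yearly hazards calibrated so that 5-year mortality matches
#' the observed per-stratum death fractions, 5 years of administrative
#' censoring, and a small independent loss-to-follow-up rate.
#'
#' @param n_subjects cohort size.
#' @param stratum_probabilities 8-vector of stratum membership
#'   probabilities (must sum to 1).
#' @param hazards_per_year 8-vector of positive per-stratum yearly hazards.
#' @param followup_horizon_years administrative censoring horizon.
#' @param random_censoring_rate yearly rate of independent censoring.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 941,
                        stratum_probabilities = c(239, 261, 182, 133, 86, 24, 9, 7) / 941,
                        hazards_per_year = -log(1 - c(4, 6, 6, 15, 19, 11, 5, 6) /
                          c(239, 261, 182, 133, 86, 24, 9, 7)) / 5,
                        followup_horizon_years = 5,
                        random_censoring_rate = 0.0023,
                        seed = 1L) {
  stopifnot(
    n_subjects >= 1,
    length(stratum_probabilities) == 8,
    abs(sum(stratum_probabilities) - 1) < 1e-8,
    length(hazards_per_year) == 8, all(hazards_per_year > 0),
    followup_horizon_years > 0, random_censoring_rate >= 0
  )
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic survival cohort
#'
#' Stratum membership is multinomial per the spec probabilities; event
#' times are exponential with the stratum's hazard; follow-up is censored
#' administratively at the horizon and by an independent exponential
#' censoring process. Marker flags are drawn uniformly among the
#' combinations consistent with each subject's stratum, and loosely
#' stratum-correlated clinical covariates (LVEF, diabetes, GRACE score)
#' are attached.
#'
#' @param spec a [cohort_spec()].
#' @return a [cohort_table()] with ground-truth attribute
#'   `hazards_per_year`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  stratum <- sample(0:7, n, replace = TRUE, prob = spec$stratum_probabilities)
  h <- spec$hazards_per_year[stratum + 1]
  t_event <- rexp(n, rate = h)
  t_cens <- if (spec$random_censoring_rate > 0) {
    rexp(n, rate = spec$random_censoring_rate)
  } else {
    rep(Inf, n)
  }
  t_cens <- pmin(t_cens, spec$followup_horizon_years)
  time_y <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  flags <- t(vapply(stratum, function(phi) {
    f <- rep(0L, 7)
    if (phi > 0) f[sample(7, phi)] <- 1L
    f
  }, integer(7)))
  colnames(flags) <- marker_flag_columns()
  df <- data.frame(
    subject_id = sprintf("synth-%05d", seq_len(n)),
    followup_days = pmax(time_y * 365.25, 0.5),
    event = event,
    polyscore = stratum,
    lvef_percent = pmin(pmax(round(rnorm(n, 53 - 2.5 * stratum, 8)), 15), 75),
    diabetes = rbinom(n, 1, pmin(0.12 + 0.04 * stratum, 0.9)),
    grace_score = pmin(pmax(round(rnorm(n, 105 + 6 * stratum, 20)), 1), 210)
  )
  df <- cbind(df, as.data.frame(flags))
  out <- cohort_table(df)
  attr(out, "hazards_per_year") <- spec$hazards_per_year
  out
}
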