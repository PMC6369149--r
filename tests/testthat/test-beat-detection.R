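test_that("impulse train at 1 Hz yields peaks at 1 s spacing", {
  fs <- 200
  n <- fs * 30
  x <- numeric(n)
  x[seq(fs, n, by = fs)] <- 1
  t <- detect_r_peaks(x, fs)
  expect_equal(length(t), 30)
  expect_lt(max(abs(diff(t) - 1)), 0.02)
})

test_that("flat signal yields no beats with a warning, not an error", {
  expect_warning(t <- detect_r_peaks(rep(0, 200 * 15), 200), "flat|no")
  expect_length(t, 0)
})

test_that("detector recovers >= 99% of synthetic beats within 20 ms", {
  syn <- synthesize_recording(quick_profile(seed = 31))
  truth <- syn$ground_truth$beat_times_s
  det <- detect_r_peaks(syn$recording$ecg[, 1], syn$recording$fs)
  nearest <- vapply(truth, function(t) min(abs(det - t)), numeric(1))
  expect_gte(mean(nearest < 0.02), 0.99)
  expect_lt(abs(length(det) - length(truth)), 0.01 * length(truth) + 1)
})

test_that("premature wide beat with compensatory pause is labelled V", {
  # regular 800 ms rhythm; beat 21 at 560 ms coupling, 1040 ms pause
  t <- c((0:19) * 0.8, 19 * 0.8 + 0.56, 19 * 0.8 + 1.6 + (0:19) * 0.8)
  widths <- rep(90, length(t))
  widths[21] <- 140
  bs <- classify_beats(beat_series(t), qrs_width_ms = widths)
  expect_equal(bs$labels[21], "V")
  expect_equal(sum(bs$labels == "V"), 1)
})

test_that("premature narrow beat with resetting pause is labelled S", {
  # coupling 560 ms, then pause 800 ms (reset; 1360 != 1600 +- 10%)
  t <- c((0:19) * 0.8, 19 * 0.8 + 0.56, 19 * 0.8 + 0.56 + 0.8 + (0:19) * 0.8)
  bs <- classify_beats(beat_series(t), qrs_width_ms = rep(90, length(t)))
  expect_equal(bs$labels[21], "S")
})

test_that("too few beats labels everything X with a warning", {
  expect_warning(bs <- classify_beats(regular_beats(10)), "fewer than 20")
  expect_true(all(bs$labels == "X"))
})

test_that("beat labels on injected ectopy reach >= 95% accuracy", {
  syn <- synthesize_recording(quick_profile(seed = 77, n_vpc = 6, n_sve = 6))
  truth <- syn$ground_truth
  res <- analyze_recording(syn$recording)
  det <- res$beats
  # align by nearest detected beat
  match_lab <- vapply(seq_along(truth$beat_times_s), function(i) {
    j <- which.min(abs(det$beat_times_s - truth$beat_times_s[i]))
    det$labels[j]
  }, character(1))
  expect_gte(mean(match_lab == truth$labels), 0.95)
  expect_equal(sum(det$labels == "V"), 6)
  expect_equal(sum(det$labels == "S"), 6)
})

test_that("filter_artifacts leaves a clean series unchanged", {
  bs <- regular_beats(100)
  expect_equal(filter_artifacts(bs)$labels, bs$labels)
})

test_that("filter_artifacts flags an implausibly short RR", {
  t <- (0:50) * 0.8
  t <- sort(c(t, t[25] + 0.15)) # inserts a 150 ms RR
  bs <- filter_artifacts(beat_series(t))
  expect_equal(sum(bs$labels == "X"), 1)
  expect_equal(bs$beat_times_s, t) # times preserved
})

test_that("filter_artifacts matches a brute-force re-implementation", {
  set.seed(12)
  rr <- rnorm(400, 800, 20)
  bump <- sample(400, 20)
  rr[bump] <- rr[bump] * sample(c(0.6, 1.5), 20, replace = TRUE)
  t <- cumsum(rr) / 1000
  got <- filter_artifacts(beat_series(t))$labels
  # independent scan implementing the stated rules
  lab <- rep("N", length(t))
  recent <- numeric(0)
  for (i in 2:length(t)) {
    ci <- 1000 * (t[i] - t[i - 1])
    if (ci < 300 || ci > 2000) {
      lab[i] <- "X"
      next
    }
    if (lab[i - 1] != "N") next
    if (length(recent) >= 5 &&
      abs(ci - median(tail(recent, 5))) > 0.25 * median(tail(recent, 5))) {
      lab[i] <- "X"
      next
    }
    recent <- c(tail(recent, 9), ci)
  }
  expect_equal(got, lab)
})

test_that("classify then filter is idempotent on a synthetic recording", {
  syn <- synthesize_recording(quick_profile(seed = 5, n_vpc = 4, n_sve = 3))
  res <- analyze_recording(syn$recording)
  bs1 <- res$beats
  widths <- measure_qrs_widths(syn$recording$ecg[, 1], syn$recording$fs,
    bs1$beat_times_s)
  bs2 <- filter_artifacts(classify_beats(bs1, qrs_width_ms = widths))
  expect_equal(bs2$labels, bs1$labels)
})

test_that("full chain recovers the ground-truth tachogram", {
  syn <- synthesize_recording(quick_profile(seed = 55))
  res <- analyze_recording(syn$recording)
  truth_rr <- syn$ground_truth$rr_ms
  det_rr <- res$beats$rr_ms
  expect_equal(length(det_rr), length(truth_rr))
  # mean absolute error below one sample period
  expect_lt(mean(abs(det_rr - truth_rr)), 1000 / syn$recording$fs)
})

test_that("systolic pressures are read from the waveform per beat", {
  fs <- 200
  n <- fs * 20
  beats <- seq(0.5, 18, by = 0.8)
  bp <- 75 + numeric(n)
  for (b in beats) {
    idx <- round((b + 0.15) * fs) + 1
    bp[(idx - 10):(idx + 10)] <- 75 +
      45 * exp(-(((idx - 10):(idx + 10)) - idx)^2 / 18)
  }
  s <- extract_systolic_pressures(bp, beats, fs)
  expect_true(all(abs(s$values_mmHg[s$valid_mask] - 120) < 0.5))
  expect_false(s$valid_mask[length(beats)]) # last beat has no window
})

test_that("programmed per-beat pressures are recovered at sample resolution", {
  syn <- synthesize_recording(quick_profile(seed = 9, pesp_fraction = 0.05))
  truth <- syn$ground_truth
  s <- extract_systolic_pressures(syn$recording$bp, truth$beat_times_s,
    syn$recording$fs)
  ok <- s$valid_mask
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(s$values_mmHg[ok] - truth$sbp_mmHg[ok])), 0.5)
})

test_that("a 0.25 Hz respiration sinusoid yields 150 breaths in 600 s", {
  fs <- 50
  t <- (0:(600 * fs - 1)) / fs
  x <- sin(2 * pi * 0.25 * t + 0.7)
  br <- detect_breaths(x, fs)
  expect_equal(length(br$breath_onset_times_s), 150)
  # expiration onsets sit at the sinusoid maxima: sin(...) = 1
  peaks <- sin(2 * pi * 0.25 * br$expiration_onset_times_s + 0.7)
  expect_gt(min(peaks), 0.99)
  # expiration onsets interleave breath onsets
  k <- findInterval(br$expiration_onset_times_s, br$breath_onset_times_s)
  expect_equal(k, seq_along(br$expiration_onset_times_s))
})

test_that("amplitude modulation does not change the breath count", {
  fs <- 50
  t <- (0:(600 * fs - 1)) / fs
  plain <- detect_breaths(sin(2 * pi * 0.25 * t + 0.7), fs)
  am <- detect_breaths(
    (1 + 0.5 * sin(2 * pi * 0.01 * t)) * sin(2 * pi * 0.25 * t + 0.7), fs
  )
  expect_equal(
    length(am$breath_onset_times_s),
    length(plain$breath_onset_times_s)
  )
})

test_that("pure noise yields an empty breath series with a warning", {
  set.seed(3)
  expect_warning(br <- detect_breaths(rnorm(50 * 300), 50),
    "irregular|no respiratory")
  expect_length(br$breath_onset_times_s, 0)
})
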