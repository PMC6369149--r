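# A beat series with hand-placed VPCs on a regular sinus background, for
# exact turbulence checks: post-pause tachogram is fully programmable.
vpc_series <- function(post_rr, n_lead = 30, base = 0.8, coupling = 0.48,
                       pause = 1.12) {
  stopifnot(length(post_rr) == 15)
  rr_s <- c(rep(base, n_lead), coupling, pause, post_rr / 1000,
    rep(base, 10))
  t <- c(0, cumsum(rr_s))
  labels <- rep("N", length(t))
  labels[n_lead + 2] <- "V"
  beat_series(t, labels)
}

test_that("TS equals the slope of an exactly linear post-pause tachogram", {
  bs <- vpc_series(800 + 10 * (1:15))
  m <- compute_turbulence_slope(bs)
  expect_true(m$evaluable)
  expect_equal(m$value, 10, tolerance = 1e-9)
  expect_false(m$abnormal) # 10 > 2.5
  expect_equal(m$n_support, 1)
})

test_that("TS of a flat post-pause tachogram is 0 and abnormal", {
  m <- compute_turbulence_slope(vpc_series(rep(820, 15)))
  expect_equal(m$value, 0)
  expect_true(m$abnormal) # 0 <= 2.5
})

test_that("TS is not evaluable without an eligible VPC", {
  m <- compute_turbulence_slope(regular_beats(100))
  expect_false(m$evaluable)
  expect_true(is.na(m$abnormal))
})

test_that("TS recovers a programmed slope from synthetic recordings", {
  syn <- synthesize_recording(
    physio_profile(turbulence_slope_ms_per_beat = 6, n_vpc = 20, seed = 61)
  )
  res <- analyze_recording(syn$recording)
  expect_lt(abs(res$markers$TS$value - 6) / 6, 0.10)
})

test_that("DC of a constant RR series is 0 and abnormal", {
  bs <- regular_beats(200)
  m <- compute_dc(bs, prsa_config(half_window_L = 10))
  expect_equal(m$value, 0)
  expect_true(m$abnormal)
})

test_that("DC on a modulated series equals the naive PRSA oracle exactly", {
  set.seed(17)
  rr_s <- (900 + 25 * sin(2 * pi * (1:400) / 6) + rnorm(400, 0, 3)) / 1000
  bs <- beat_series(c(0, cumsum(rr_s)))
  cfg <- prsa_config(half_window_L = 10)
  m <- compute_dc(bs, cfg)
  anchors <- select_anchors(bs$rr_ms, "rr_increase", cfg,
    valid_mask = rep(TRUE, length(bs$rr_ms)))
  X <- naive_prsa(bs$rr_ms, anchors, 10)
  want <- unname((X["0"] + X["1"] - X["-1"] - X["-2"]) / 4)
  expect_equal(m$value, want, tolerance = 1e-12)
  expect_gt(m$value, 0)
})

test_that("DC at exactly 2.5 ms is abnormal (boundary on the abnormal side)", {
  thr <- default_thresholds()
  expect_true(dichotomize(2.5, thr$DC))
  expect_false(dichotomize(2.5000001, thr$DC))
})

test_that("BRS with zero RR response is 0 and abnormal", {
  n <- 300
  t <- (0:(n - 1)) * 0.9
  bs <- beat_series(t)
  sbp <- sbp_series(120 + 5 * sin(2 * pi * (1:n) / 11))
  m <- compute_brs(bs, sbp)
  expect_equal(m$value, 0)
  expect_true(m$abnormal)
})

test_that("BRS recovers programmed gains on the normal and abnormal side", {
  syn <- synthesize_recording(quick_profile(brs_gain_ms_per_mmHg = 10, seed = 3))
  res <- analyze_recording(syn$recording)
  expect_lt(abs(res$markers$BRS$value - 10) / 10, 0.10)
  expect_false(res$markers$BRS$abnormal)
  syn <- synthesize_recording(quick_profile(brs_gain_ms_per_mmHg = 1, seed = 4))
  res <- analyze_recording(syn$recording)
  expect_lt(abs(res$markers$BRS$value - 1), 0.3)
  expect_true(res$markers$BRS$abnormal)
})

test_that("respiration rate is breath count in the last 10 min over 10", {
  br <- breath_series(seq(5, 1795, length.out = 450), numeric(0))
  # onsets in [1200, 1800): spacing ~3.99 s -> 150 in the window
  m <- compute_respiration_rate(br, 1800)
  expect_equal(m$value, sum(br$breath_onset_times_s >= 1200) / 10)
  expect_false(m$abnormal)
})

test_that("respiration boundary 18.6 breaths/min is abnormal", {
  onsets <- 1200 + (0:185) * (600 / 186) + 0.5
  m <- compute_respiration_rate(breath_series(onsets, numeric(0)), 1800)
  expect_equal(m$value, 18.6)
  expect_true(m$abnormal)
})

test_that("a 0.31 Hz respiration sinusoid measures exactly 18.6 breaths/min", {
  syn <- synthesize_recording(
    physio_profile(resp_rate_bpm = 18.6, seed = 29)
  )
  res <- analyze_recording(syn$recording)
  expect_equal(res$markers$RESP$value, 18.6)
  expect_true(res$markers$RESP$abnormal)
})

test_that("ETA of a constant RR series is 0 and abnormal", {
  bs <- regular_beats(200, rr_s = 0.9)
  br <- breath_series(seq(2, 170, by = 4), seq(3, 171, by = 4))
  m <- compute_eta(bs, br, prsa_config(half_window_L = 10))
  expect_equal(m$value, 0)
  expect_true(m$abnormal)
})

test_that("ETA separates strong from near-absent RSA", {
  syn <- synthesize_recording(quick_profile(rsa_amplitude_ms = 20, seed = 41))
  res <- analyze_recording(syn$recording)
  expect_gt(res$markers$ETA$value, 0.19)
  expect_false(res$markers$ETA$abnormal)
  syn <- synthesize_recording(quick_profile(rsa_amplitude_ms = 0.1,
    rr_jitter_ms = 1, seed = 42))
  res <- analyze_recording(syn$recording)
  expect_true(res$markers$ETA$abnormal)
})

test_that("PESP ratio follows its arithmetic definition", {
  # one VPC; post-ectopic SBP 120, following five sinus SBPs 115
  rr_s <- c(rep(0.8, 30), 0.48, 1.12, rep(0.8, 20))
  t <- c(0, cumsum(rr_s))
  labels <- rep("N", length(t))
  labels[32] <- "V"
  bs <- beat_series(t, labels)
  sbp_vals <- rep(115, length(t))
  sbp_vals[33] <- 120
  m <- compute_pesp(bs, sbp_series(sbp_vals))
  expect_equal(m$value, 120 / 115, tolerance = 1e-12)
  expect_true(m$abnormal) # 1.0435 >= 1.03
  sbp_all_equal <- sbp_series(rep(115, length(t)))
  m2 <- compute_pesp(bs, sbp_all_equal)
  expect_equal(m2$value, 1)
  expect_false(m2$abnormal)
})

test_that("PESP recovers a programmed +8% potentiation within 2%", {
  syn <- synthesize_recording(quick_profile(pesp_fraction = 0.08,
    n_vpc = 8, seed = 19))
  res <- analyze_recording(syn$recording)
  expect_lt(abs(res$markers$PESP$value - 1.08) / 1.08, 0.02)
  expect_true(res$markers$PESP$abnormal)
})

test_that("ectopy dichotomy uses strict inequalities on both counts", {
  mk <- function(n_s, n_v) {
    labels <- c(rep("N", 400), rep("S", n_s), rep("V", n_v))
    t <- seq(0, by = 0.9, length.out = length(labels))
    beat_series(t, labels)
  }
  m <- compute_ectopy(mk(8, 0), 1800)
  expect_true(m$abnormal)
  m <- compute_ectopy(mk(7, 29), 1800)
  expect_false(m$abnormal) # boundary: strict >
  m <- compute_ectopy(mk(0, 30), 1800)
  expect_true(m$abnormal)
  # scaling to the 30-min equivalent
  m <- compute_ectopy(mk(4, 0), 900)
  expect_equal(unname(m$value["sve"]), 8)
  expect_true(m$abnormal)
})

test_that("dichotomize honours the printed boundary semantics", {
  thr <- default_thresholds()
  expect_true(dichotomize(2.5, thr$TS))
  expect_true(dichotomize(18.6, thr$RESP))
  expect_false(dichotomize(0.20, thr$ETA))
  expect_true(dichotomize(0.19, thr$ETA))
  expect_true(is.na(dichotomize(NA_real_, thr$TS)))
})

test_that("markers scale equivariantly with the RR series", {
  set.seed(23)
  rr_s <- (900 + 25 * sin(2 * pi * (1:500) / 6) + rnorm(500, 0, 4)) / 1000
  bs1 <- beat_series(c(0, cumsum(rr_s)))
  c_scale <- 1.2
  bs2 <- beat_series(c(0, cumsum(rr_s * c_scale)))
  cfg <- prsa_config(half_window_L = 10)
  dc1 <- compute_dc(bs1, cfg)$value
  dc2 <- compute_dc(bs2, cfg)$value
  expect_equal(dc2, c_scale * dc1, tolerance = 1e-9)
  e1 <- compute_ectopy(bs1, 450)
  e2 <- compute_ectopy(bs2, 450)
  expect_equal(e1$value, e2$value)
})

test_that("marker recovery correlates with randomized ground truth", {
  set.seed(501)
  n_rec <- 30
  gains <- runif(n_rec, 1, 15)
  slopes <- runif(n_rec, 3, 12)
  rates <- runif(n_rec, 10, 24)
  pesps <- runif(n_rec, 0, 0.1)
  got <- t(vapply(seq_len(n_rec), function(i) {
    syn <- synthesize_recording(quick_profile(
      brs_gain_ms_per_mmHg = gains[i],
      turbulence_slope_ms_per_beat = slopes[i],
      resp_rate_bpm = rates[i],
      pesp_fraction = pesps[i],
      n_vpc = 8,
      seed = 1000 + i
    ))
    res <- analyze_recording(syn$recording)
    c(
      brs = res$markers$BRS$value, ts = res$markers$TS$value,
      resp = res$markers$RESP$value, pesp = res$markers$PESP$value
    )
  }, numeric(4)))
  expect_gt(cor(got[, "brs"], gains), 0.9)
  expect_gt(cor(got[, "ts"], slopes), 0.9)
  expect_gt(cor(got[, "resp"], rates), 0.9)
  expect_gt(cor(got[, "pesp"], 1 + pesps), 0.9)
})
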