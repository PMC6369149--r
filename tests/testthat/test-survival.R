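test_that("KM matches the hand product-limit on uncensored toy data", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
})

test_that("KM handles censoring by the product-limit rule", {
  # deaths at 1 and 3, censored at 2 and 3: S(3) = (3/4) * (1/2)
  km <- km_estimate(c(1, 2, 3, 3), c(1, 0, 1, 0))
  expect_equal(km$surv[km$time == 3][1], 0.375)
})

test_that("an all-censored sample gives a flat curve at 1", {
  km <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km$surv == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(30)
  t <- rexp(200, 0.2)
  km <- km_estimate(t, rep(1, 200))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("KM confidence bounds bracket the estimate and survival decreases", {
  set.seed(31)
  t <- rexp(100, 0.3)
  e <- rbinom(100, 1, 0.8)
  km <- km_estimate(t, e, at_risk_grid = c(0, 2, 4))
  expect_true(all(diff(km$surv) <= 1e-12))
  inner <- km$surv < 1 & km$surv > 0
  expect_true(all(km$lower[inner] <= km$surv[inner] + 1e-12))
  expect_true(all(km$upper[inner] >= km$surv[inner] - 1e-12))
  expect_true(all(diff(km$at_risk$n_risk) <= 0))
})

test_that("log-rank of two identical groups is zero", {
  t <- c(1, 2, 3, 4, 5)
  e <- c(1, 1, 0, 1, 0)
  lr <- logrank_test(c(t, t), c(e, e), rep(1:2, each = 5))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$df, 1)
})

test_that("log-rank matches the hand observed-minus-expected table", {
  # groups A: deaths at 1, 2, censored 4; B: deaths at 3, 5, censored 6
  times <- c(1, 2, 4, 3, 5, 6)
  events <- c(1, 1, 0, 1, 1, 0)
  groups <- c("A", "A", "A", "B", "B", "B")
  # hand 2x2 per event time, tracking group A:
  # t=1: nA=3 nB=3, death in A -> O=1, E=3/6, V=3*3*5/(36*5)
  # t=2: nA=2 nB=3, death in A -> O=1, E=2/5, V=2*3*4/(25*4)
  # t=3: nA=1 nB=3, death in B -> O=0, E=1/4, V=1*3*3/(16*3)
  # t=5: nA=0 nB=2, death in B -> O=0, E=0,   V=0
  o_minus_e <- (1 - 3 / 6) + (1 - 2 / 5) + (0 - 1 / 4) + 0
  v <- 3 * 3 * 5 / (36 * 5) + 2 * 3 * 4 / (25 * 4) + 1 * 3 * 3 / (16 * 3)
  want <- o_minus_e^2 / v
  lr <- logrank_test(times, events, groups)
  expect_equal(lr$chisq, want, tolerance = 1e-10)
})

test_that("log-rank rejects degenerate group structures", {
  expect_error(logrank_test(c(1, 2), c(1, 1), c("A", "A")), "2 non-empty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "event")
})

test_that("Cox HR for a binary covariate matches a grid-search oracle", {
  x <- c(0, 0, 0, 1, 1, 1)
  times <- c(5.1, 7.3, 9.2, 1.4, 2.8, 6.6)
  events <- c(1, 0, 1, 1, 1, 0)
  fit <- cox_fit(data.frame(x = x), times, events)
  grid <- seq(-4, 4, by = 1e-3)
  ll <- vapply(grid, cox_partial_loglik, numeric(1), x = x, times = times,
    events = events)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-6)
  llf <- vapply(fine, cox_partial_loglik, numeric(1), x = x, times = times,
    events = events)
  beta_star <- fine[which.max(llf)]
  expect_equal(fit$coefficients$hr, exp(beta_star), tolerance = 1e-4)
})

test_that("a constant covariate is rejected", {
  expect_error(
    cox_fit(data.frame(x = rep(0, 6)), 1:6, rep(1, 6)),
    "constant"
  )
})

test_that("Cox recovers a known hazard ratio per Polyscore point", {
  set.seed(33)
  n <- 1000
  score <- sample(0:7, n, replace = TRUE, prob = c(8, 8, 6, 4, 3, 2, 1, 1))
  h <- 0.02 * 2^score
  t <- rexp(n, h)
  cens <- pmin(rexp(n, 0.01), 5)
  times <- pmin(t, cens)
  events <- as.integer(t <= cens)
  fit <- cox_fit(data.frame(polyscore = score), times, events)
  expect_gt(fit$coefficients$hr, 1.8)
  expect_lt(fit$coefficients$hr, 2.2)
})

test_that("binary-covariate Cox converges to the event-rate ratio", {
  set.seed(34)
  n <- 2000
  x <- rep(c(0, 1), each = n / 2)
  t <- rexp(n, ifelse(x == 1, 0.3, 0.1))
  fit <- cox_fit(data.frame(x = x), t, rep(1, n))
  expect_lt(abs(fit$coefficients$hr - 3) / 3, 0.10)
})

test_that("identical strata give a stratum hazard ratio of 1", {
  df <- data.frame(
    subject_id = sprintf("s%d", 1:40),
    followup_days = rep(c(100, 200, 300, 400), 10),
    event = rep(c(1, 0), 20),
    polyscore = rep(c(0, 3), each = 20)
  )
  df$followup_days[df$polyscore == 3] <- df$followup_days[df$polyscore == 0]
  df$event[df$polyscore == 3] <- df$event[df$polyscore == 0]
  shr <- stratum_hazard_ratios(cohort_table(df))
  expect_equal(shr$hr[shr$stratum == 3], 1, tolerance = 1e-6)
  # strata 1, 2, 4..7 are empty: not evaluable
  expect_true(all(is.na(shr$hr[shr$stratum != 3])))
  expect_equal(nrow(shr), 7)
})

test_that("per-stratum log hazard ratios track a programmed exponential ladder", {
  spec <- cohort_spec(
    n_subjects = 5000,
    hazards_per_year = 0.02 * 6^((0:7) / 3),
    seed = 77
  )
  co <- generate_cohort(spec)
  shr <- stratum_hazard_ratios(co)
  fit <- hr_ladder_slope(shr, d0 = sum(co$event[co$polyscore == 0]))
  expect_lt(abs(fit$slope - log(6) / 3), 2.5 * fit$se)
  # and the per-point Cox coefficient agrees with the programmed ln(6)/3
  cx <- cox_fit(data.frame(polyscore = co$polyscore), co$followup_days,
    co$event)
  expect_equal(cx$coefficients$coef, log(6) / 3, tolerance = 0.1)
})

test_that("optimize_dichotomy finds a perfectly separating threshold", {
  # deaths (early) all carry values > 20; survivors censored late
  values <- c(1:10, 21:30)
  times <- c(rep(50, 10), 1:10)
  events <- c(rep(0, 10), rep(1, 10))
  opt <- optimize_dichotomy(values, times, events)
  expect_gt(opt$threshold, 10)
  expect_lt(opt$threshold, 21)
})

test_that("optimize_dichotomy equals an exhaustive log-rank scan", {
  set.seed(35)
  values <- round(runif(20, 0, 10), 1)
  times <- rexp(20, 0.1 + 0.05 * values)
  events <- rbinom(20, 1, 0.8)
  grid <- sort(unique(values))
  grid <- (grid[-1] + grid[-length(grid)]) / 2
  opt <- optimize_dichotomy(values, times, events, candidate_grid = grid)
  best <- -Inf
  best_thr <- NA
  best_n <- Inf
  for (thr in grid) {
    abn <- values >= thr
    if (sum(abn) %in% c(0, length(values))) next
    chi <- logrank_test(times, events, abn)$chisq
    if (chi > best + 1e-12 ||
      (abs(chi - best) <= 1e-12 && sum(abn) < best_n)) {
      best <- chi
      best_thr <- thr
      best_n <- sum(abn)
    }
  }
  expect_equal(opt$threshold, best_thr)
  expect_equal(opt$chisq, best, tolerance = 1e-10)
})

test_that("optimize_dichotomy is invariant under monotone transformation", {
  set.seed(36)
  values <- runif(30, 1, 5)
  times <- rexp(30, 0.05 * values)
  events <- rep(1, 30)
  g1 <- sort(unique(values))
  g1 <- (g1[-1] + g1[-length(g1)]) / 2
  o1 <- optimize_dichotomy(values, times, events, g1)
  o2 <- optimize_dichotomy(exp(values), times, events, exp(g1))
  expect_equal(o2$threshold, exp(o1$threshold), tolerance = 1e-9)
  expect_equal(o2$chisq, o1$chisq, tolerance = 1e-9)
})

test_that("degenerate dichotomy inputs are rejected", {
  expect_error(optimize_dichotomy(rep(3, 20), rexp(20), rep(1, 20)),
    "distinct")
  expect_error(optimize_dichotomy(1:5, rexp(5), rep(1, 5)), "10 subjects")
})

paper_counts_cohort <- function() {
  counts <- c(239, 261, 182, 133, 86, 24, 9, 7)
  deaths <- c(4, 6, 6, 15, 19, 11, 5, 6)
  rows <- do.call(rbind, lapply(0:7, function(phi) {
    n <- counts[phi + 1]
    d <- deaths[phi + 1]
    data.frame(
      subject_id = sprintf("p%d_%d", phi, seq_len(n)),
      followup_days = rep(1826, n),
      event = c(rep(1, d), rep(0, n - d)),
      polyscore = phi
    )
  }))
  cohort_table(rows)
}

test_that("cohort_summary reproduces the published stratum percentages", {
  cs <- cohort_summary(paper_counts_cohort())
  expect_equal(round(cs$strata$pct_of_cohort, 1),
    c(25.4, 27.7, 19.3, 14.1, 9.1, 2.6, 1.0, 0.7))
  expect_equal(round(cs$strata$pct_dead, 1),
    c(1.7, 2.3, 3.3, 11.3, 22.1, 45.8, 55.6, 85.7))
  expect_equal(cs$overall$n, 941)
  expect_equal(cs$overall$deaths, 72)
  expect_equal(round(cs$overall$pct_dead, 2), 7.65)
})

test_that("a single-subject cohort without events has zero mortality", {
  df <- data.frame(subject_id = "only", followup_days = 100, event = 0,
    polyscore = 2)
  cs <- cohort_summary(cohort_table(df))
  expect_equal(cs$overall$pct_dead, 0)
  expect_error(cohort_summary(cohort_table(df[0, ])), "empty")
})

test_that("marker contribution profile matches brute-force tabulation", {
  co <- generate_cohort(cohort_spec(n_subjects = 600, seed = 41))
  prof <- marker_contribution_profile(co)
  fl <- c("flag_ts", "flag_dc", "flag_brs", "flag_resp", "flag_eta",
    "flag_pesp", "flag_ectopy")
  for (phi in 1:7) {
    g <- co[co$polyscore == phi, fl]
    if (!nrow(g)) {
      expect_true(all(is.na(prof[phi, ])))
    } else {
      expect_equal(unname(prof[phi, ]), unname(colMeans(as.matrix(g))))
    }
  }
  # stratum 7 forces every marker positive; per-subject flags sum to phi
  if (any(co$polyscore == 7)) expect_true(all(prof[7, ] == 1))
  expect_equal(unname(rowMeans(prof)), (1:7) / 7, tolerance = 1e-12)
})
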