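# Shared fixtures built in code.

# Short, light profile for unit tests: 700 s at 200 Hz keeps each
# synthesis + analysis well under a second while all markers stay
# evaluable (>= 600 s for the respiration window).
quick_profile <- function(...) {
  args <- list(duration_s = 700, fs = 200, n_vpc = 4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(physio_profile, args)
}

# Regular sinus beat series with optional inserted ectopic patterns.
regular_beats <- function(n = 60, rr_s = 0.8, t0 = 0) {
  beat_series(t0 + (0:(n - 1)) * rr_s)
}

# Naive PRSA: the O(n * L) double-loop reference used as the independent
# oracle for prsa_average.
naive_prsa <- function(target, anchors, L) {
  offsets <- -L:(L - 1)
  X <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    acc <- 0
    for (a in anchors) acc <- acc + target[a + offsets[k]]
    X[k] <- acc / length(anchors)
  }
  setNames(X, offsets)
}

# Weighted least-squares slope (through the origin) of log hazard ratio
# versus stratum, with a standard error that accounts for the correlation
# induced by the shared stratum-0 reference group: for ratio estimates
# against a common control, cov(log HR_i, log HR_j) ~ 1/d0 (d0 = events in
# the reference stratum), while var(log HR_i) comes from each fit's CI.
hr_ladder_slope <- function(shr, d0) {
  ok <- is.finite(shr$hr) & is.finite(shr$lower) & shr$lower > 0
  phi <- shr$stratum[ok]
  y <- log(shr$hr[ok])
  se <- (log(shr$upper[ok]) - log(shr$lower[ok])) / (2 * qnorm(0.975))
  w <- 1 / se^2
  denom <- sum(w * phi^2)
  a <- w * phi / denom
  slope <- sum(a * y)
  Sigma <- matrix(1 / d0, length(phi), length(phi))
  diag(Sigma) <- se^2
  list(slope = slope, se = sqrt(drop(t(a) %*% Sigma %*% a)), n = sum(ok))
}

# Cox partial log-likelihood for a single covariate, no ties assumed
# (Efron = Breslow); used for grid-search oracles.
cox_partial_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
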