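## Cohort validation layer: Kaplan-Meier, log-rank, Cox proportional
## hazards, per-stratum hazard ratios vs stratum 0, log-rank cutoff
## optimization, cohort summaries and marker-contribution profiles.
## Estimation is delegated to the 'survival' package; this layer fixes the
## contracts (log(-log) KM intervals, Efron ties, per-stratum indicator
## fits) used throughout.

#' Kaplan-Meier estimate with 95% pointwise confidence intervals
#'
#' Product-limit estimator with Greenwood variance and log(-log)
#' (complementary log-log) transformed 95% pointwise confidence intervals.
#'
#' @param times follow-up times (> 0).
#' @param events 0/1 event indicators (1 = death).
#' @param at_risk_grid optional time grid at which numbers at risk are
#'   reported.
#' @return Object of class `km_curve`: `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`, and `at_risk` (data.frame) when a grid is given.
#' @export
km_estimate <- function(times, events, at_risk_grid = NULL) {
  stopifnot(length(times) >= 1, all(times > 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = if (any(events == 1)) "log-log" else "none"
  )
  s <- summary(fit, censored = TRUE)
  out <- list(
    time = s$time, surv = s$surv,
    lower = if (!is.null(s$lower)) s$lower else rep(1, length(s$time)),
    upper = if (!is.null(s$upper)) s$upper else rep(1, length(s$time)),
    n_risk = s$n.risk, n_event = s$n.event
  )
  if (!is.null(at_risk_grid)) {
    nr <- vapply(at_risk_grid, function(t) sum(times >= t), numeric(1))
    out$at_risk <- data.frame(time = at_risk_grid, n_risk = nr)
  }
  structure(out, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "<km_curve> %d time points, S(final) = %.3f\n",
    length(x$time), tail(x$surv, 1)
  ))
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param groups group membership vector (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("log-rank test needs >= 2 non-empty groups")
  if (sum(events) < 1) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
    p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization via `survival::coxph` (Newton-Raphson)
#' with Efron (default) or Breslow handling of ties. Per covariate the
#' hazard ratio, its 95% confidence interval, the Wald chi-square and its
#' p-value are reported.
#'
#' @param covariates numeric matrix or data.frame of covariates (one
#'   column per covariate; constant columns are an error).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `cox_fit`: data.frame `coefficients` with
#'   columns `term`, `coef`, `hr`, `lower`, `upper`, `wald_chisq`, `p`;
#'   plus `model_chisq` (likelihood-ratio), `n`, `n_event`, `ties`,
#'   `model_type`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.data.frame(covariates)
  if (!ncol(X)) stop("no covariates supplied")
  const <- vapply(X, function(c) length(unique(c[!is.na(c)])) < 2, logical(1))
  if (any(const)) {
    stop("covariate(s) constant across subjects: ",
      paste(names(X)[const], collapse = ", "))
  }
  if (sum(events) < 1) stop("Cox model needs at least one event")
  dat <- cbind(X, .time = times, .event = events)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = dat, ties = ties,
    control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$fail)) stop("Cox model did not converge")
  co <- coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  wald <- (co / se)^2
  coefs <- data.frame(
    term = names(co),
    coef = unname(co),
    hr = unname(exp(co)),
    lower = unname(exp(co - z * se)),
    upper = unname(exp(co + z * se)),
    wald_chisq = unname(wald),
    p = unname(pchisq(wald, 1, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      coefficients = coefs,
      model_chisq = unname(2 * diff(fit$loglik)),
      n = fit$n, n_event = fit$nevent, ties = ties,
      model_type = if (ncol(X) > 1) "multivariable" else "univariable"
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> %s, %d subjects, %d events, ties=%s\n",
    x$model_type, x$n, x$n_event, x$ties
  ))
  df <- x$coefficients
  df$hr <- signif(df$hr, 4)
  df$lower <- signif(df$lower, 4)
  df$upper <- signif(df$upper, 4)
  df$wald_chisq <- signif(df$wald_chisq, 4)
  df$p <- signif(df$p, 3)
  print(df[c("term", "hr", "lower", "upper", "wald_chisq", "p")],
    row.names = FALSE)
  invisible(x)
}

#' Per-stratum hazard ratios vs Polyscore 0
#'
#' For each stratum phi = 1..7, a univariable Cox model on the indicator
#' covariate restricted to subjects in strata {0, phi}. Strata with no
#' subjects (or no events in either group of the pair) are reported as
#' not evaluable (`NA` row).
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with columns `stratum`, `n`, `events`, `hr`,
#'   `lower`, `upper`, `wald_chisq`, `p`.
#' @export
stratum_hazard_ratios <- function(cohort) {
  ref <- cohort[cohort$polyscore == 0 & !is.na(cohort$polyscore), ]
  if (!nrow(ref)) stop("stratum 0 is empty; no reference group")
  rows <- lapply(1:7, function(phi) {
    g <- cohort[!is.na(cohort$polyscore) & cohort$polyscore == phi, ]
    base <- data.frame(
      stratum = phi, n = nrow(g), events = sum(g$event),
      hr = NA_real_, lower = NA_real_, upper = NA_real_,
      wald_chisq = NA_real_, p = NA_real_
    )
    if (!nrow(g)) return(base)
    sub <- rbind(ref, g)
    if (sum(sub$event) < 1) return(base)
    fit <- tryCatch(
      cox_fit(
        data.frame(stratum_ind = as.numeric(sub$polyscore == phi)),
        sub$followup_days, sub$event
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(base)
    co <- fit$coefficients
    base$hr <- co$hr
    base$lower <- co$lower
    base$upper <- co$upper
    base$wald_chisq <- co$wald_chisq
    base$p <- co$p
    base
  })
  do.call(rbind, rows)
}

#' Log-rank-optimal dichotomy of a continuous marker
#'
#' Scans candidate thresholds and returns the one maximizing the two-group
#' log-rank chi-square for the split "value >= threshold" (abnormal side
#' configurable). Degenerate splits (an empty side) are skipped; ties are
#' broken toward the threshold yielding the smaller abnormal group.
#'
#' @param values continuous marker values (>= 2 distinct; >= 10 subjects).
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param candidate_grid candidate thresholds; defaults to midpoints of
#'   consecutive sorted unique values.
#' @param abnormal_side `"at_or_above"` (default) or `"below_or_equal"`.
#' @return list with `threshold`, `chisq`, and the full `scan` data.frame.
#' @export
optimize_dichotomy <- function(values, times, events, candidate_grid = NULL,
                               abnormal_side = c("at_or_above", "below_or_equal")) {
  abnormal_side <- match.arg(abnormal_side)
  if (length(values) < 10) stop("optimize_dichotomy needs >= 10 subjects")
  u <- sort(unique(values))
  if (length(u) < 2) stop("optimize_dichotomy needs >= 2 distinct values")
  if (is.null(candidate_grid)) {
    candidate_grid <- (u[-1] + u[-length(u)]) / 2
  }
  scan <- lapply(candidate_grid, function(thr) {
    abn <- if (abnormal_side == "at_or_above") values >= thr else values <= thr
    n_abn <- sum(abn)
    if (n_abn == 0 || n_abn == length(values)) {
      return(data.frame(threshold = thr, chisq = NA_real_, n_abnormal = n_abn))
    }
    chisq <- tryCatch(
      logrank_test(times, events, abn)$chisq,
      error = function(e) NA_real_
    )
    data.frame(threshold = thr, chisq = chisq, n_abnormal = n_abn)
  })
  scan <- do.call(rbind, scan)
  ok <- which(is.finite(scan$chisq))
  if (!length(ok)) stop("no admissible threshold in the candidate grid")
  best_chi <- max(scan$chisq[ok])
  cand <- ok[scan$chisq[ok] >= best_chi - 1e-12]
  best <- cand[which.min(scan$n_abnormal[cand])]
  list(threshold = scan$threshold[best], chisq = scan$chisq[best],
    scan = scan)
}

#' Cohort summary by Polyscore stratum
#'
#' Per-stratum patient counts, percentages of the cohort, death counts and
#' percent dead, plus overall totals and median/IQR summaries of the
#' continuous covariates present.
#'
#' @param cohort a [cohort_table()].
#' @return list with `strata` (data.frame over strata 0-7), `overall`, and
#'   `continuous` (median/IQR table).
#' @export
cohort_summary <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort")
  n_total <- nrow(cohort)
  strata <- do.call(rbind, lapply(0:7, function(phi) {
    g <- cohort[!is.na(cohort$polyscore) & cohort$polyscore == phi, ]
    n <- nrow(g)
    d <- sum(g$event)
    data.frame(
      stratum = phi, n = n,
      pct_of_cohort = 100 * n / n_total,
      deaths = d,
      pct_dead = if (n > 0) 100 * d / n else NA_real_
    )
  }))
  overall <- data.frame(
    n = n_total, deaths = sum(cohort$event),
    pct_dead = 100 * sum(cohort$event) / n_total
  )
  cont_cols <- intersect(
    c("followup_days", "lvef_percent", "grace_score"), names(cohort)
  )
  continuous <- do.call(rbind, lapply(cont_cols, function(cl) {
    x <- cohort[[cl]]
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(variable = cl, median = q[2], q1 = q[1], q3 = q[3],
      row.names = NULL)
  }))
  list(strata = strata, overall = overall, continuous = continuous)
}

#' Marker-contribution profile across Polyscore strata
#'
#' For each stratum phi = 1..7 and each of the seven markers, the fraction
#' of patients in the stratum with that marker abnormal. Strata without
#' subjects yield `NA` rows.
#'
#' @param cohort a [cohort_table()] carrying the seven `flag_*` columns.
#' @return 7 x 7 numeric matrix, rows = strata 1..7, columns = markers.
#' @export
marker_contribution_profile <- function(cohort) {
  fl <- marker_flag_columns()
  if (!all(fl %in% names(cohort))) {
    stop("cohort lacks marker flag columns: ",
      paste(setdiff(fl, names(cohort)), collapse = ", "))
  }
  m <- t(vapply(1:7, function(phi) {
    g <- cohort[!is.na(cohort$polyscore) & cohort$polyscore == phi, fl]
    if (!nrow(g)) return(rep(NA_real_, 7))
    colMeans(as.matrix(g))
  }, numeric(7)))
  dimnames(m) <- list(
    paste0("stratum_", 1:7),
    c("TS", "DC", "BRS", "RESP", "ETA", "PESP", "ECTOPY")
  )
  m
}

#' Plot a Kaplan-Meier curve (probability of death)
#'
#' Base-graphics plot of `1 - S(t)` with its 95% pointwise confidence
#' band, optionally annotated with numbers at risk.
#'
#' @param x a `km_curve`.
#' @param xlab,ylab,main usual plot labels.
#' @param ... further args to [plot()].
#' @return invisibly, `x`.
#' @export
plot.km_curve <- function(x, xlab = "Follow-up", ylab = "Probability of death",
                          main = "", ...) {
  t <- c(0, x$time)
  f <- 1 - c(1, x$surv)
  plot(t, f, type = "s", ylim = c(0, max(0.05, 1.05 * max(f))),
    xlab = xlab, ylab = ylab, main = main, ...)
  lines(c(0, x$time), 1 - c(1, x$lower), type = "s", lty = 2, col = "grey40")
  lines(c(0, x$time), 1 - c(1, x$upper), type = "s", lty = 2, col = "grey40")
  if (!is.null(x$at_risk)) {
    mtext(paste(x$at_risk$n_risk, collapse = "  "), side = 1, line = 3,
      cex = 0.7)
  }
  invisible(x)
}

#' Plot per-stratum hazard ratios on a log scale
#'
#' Fig-3-style ladder: hazard ratio of each Polyscore stratum vs stratum 0
#' with 95% confidence intervals, log-scaled vertical axis.
#'
#' @param shr data.frame from [stratum_hazard_ratios()].
#' @param ... further args to [plot()].
#' @return invisibly, `shr`.
#' @export
plot_stratum_hazard_ratios <- function(shr, ...) {
  ok <- is.finite(shr$hr)
  ylim <- range(c(shr$lower[ok], shr$upper[ok], 1), na.rm = TRUE)
  plot(shr$stratum[ok], shr$hr[ok], log = "y", pch = 19,
    xlab = "Polyscore stratum", ylab = "Hazard ratio vs stratum 0",
    ylim = ylim, xlim = c(0.5, 7.5), ...)
  segments(shr$stratum[ok], shr$lower[ok], shr$stratum[ok], shr$upper[ok])
  abline(h = 1, lty = 3)
  invisible(shr)
}

#' Plot marker-contribution profiles
#'
#' Fig-2-style profiles: for each marker, the fraction of patients positive
#' within each Polyscore stratum.
#'
#' @param profile matrix from [marker_contribution_profile()].
#' @param ... further args to [matplot()].
#' @return invisibly, `profile`.
#' @export
plot_marker_contributions <- function(profile, ...) {
  matplot(1:7, profile, type = "b", pch = 1:7, lty = 1,
    xlab = "Polyscore stratum", ylab = "Fraction positive",
    ylim = c(0, 1), ...)
  legend("topleft", colnames(profile), pch = 1:7, col = 1:7, cex = 0.8,
    bty = "n")
  invisible(profile)
}
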