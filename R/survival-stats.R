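#' Kaplan-Meier estimate with median and confidence interval
#'
#' Product-limit estimator of overall survival.  The median is the first
#' time at which the estimated survival drops to 0.5 or below; when the
#' curve never reaches 0.5 the median is "not reached".  The confidence
#' interval for the median uses the Brookmeyer-Crowley construction on the
#' log-log scale.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical/0-1 event (death) indicators.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"km_summary"`: `curve` (data frame with
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`), `median`
#'   (numeric, NA when not reached), `median_reached`, `median_ci`
#'   (2-vector, NA where undefined), `n`, `n_events`.
#' @examples
#' km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))$median  # 2
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(is.na(times) | is.na(events)) || any(times < 0))
    stop("times must be non-negative and complete", call. = FALSE)
  events <- as.integer(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  q <- quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  structure(list(
    curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper),
    median = med,
    median_reached = !is.na(med),
    median_ci = c(unname(q$lower), unname(q$upper)),
    n = length(times), n_events = sum(events)
  ), class = "km_summary")
}

#' @export
print.km_summary <- function(x, ...) {
  med <- if (x$median_reached) {
    ci <- ifelse(is.na(x$median_ci), "NR", format(x$median_ci))
    sprintf("%g (95%% CI %s-%s)", x$median, ci[1], ci[2])
  } else "not reached"
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median = %s\n",
              x$n, x$n_events, med))
  invisible(x)
}

#' Log-rank test
#'
#' Standard k-group log-rank chi-square comparing survival curves.
#'
#' @inheritParams km_estimate
#' @param groups Group labels, at least two distinct values.
#' @return List with `statistic`, `df`, `p` and `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("log-rank test needs at least two groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  df <- length(sd$n) - 1L
  list(statistic = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE),
       n_per_group = setNames(as.vector(sd$n), levels(droplevels(groups))))
}

#' Cox hazard ratio for a binary contrast
#'
#' Cox proportional-hazards fit of a two-level indicator using the Efron
#' tie correction, with Wald confidence interval and p-value.  When one
#' arm has no events the partial likelihood is monotone and the estimate
#' diverges; the result is flagged rather than trusted.
#'
#' @inheritParams km_estimate
#' @param indicator Logical/0-1 vector; the hazard ratio is for
#'   `indicator == 1` versus `indicator == 0`.
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `hr`, `ci` (2-vector), `p`, `loglik` (fitted model
#'   log partial likelihood), `loglik_null`, `n_per_arm`, `events_per_arm`
#'   and `monotone` (TRUE when an arm has no events).
#' @export
cox_binary <- function(times, events, indicator, conf_level = 0.95) {
  stopifnot(length(times) == length(events),
            length(times) == length(indicator))
  ind <- as.integer(indicator)
  if (!all(ind %in% 0:1)) stop("indicator must be binary", call. = FALSE)
  events <- as.integer(events)
  ev_arm <- c(sum(events[ind == 0]), sum(events[ind == 1]))
  fit <- survival::coxph(survival::Surv(times, events) ~ ind, ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta),
       ci = exp(beta + c(-1, 1) * z * se),
       p = 2 * pnorm(-abs(beta / se)),
       loglik = fit$loglik[2], loglik_null = fit$loglik[1],
       n_per_arm = c(sum(ind == 0), sum(ind == 1)),
       events_per_arm = ev_arm,
       monotone = any(ev_arm == 0))
}

# Per-subject decomposition of Harrell's concordance.  For each subject
# the counts of concordant / risk-tied / comparable pairs it takes part in
# are returned, so leave-one-out concordances follow by subtraction.
# Comparable pairs: the earlier time is an event; tied times are
# comparable only when exactly one of the two is an event (the event
# subject is taken as failing first).  Risk ties count 0.5.
.concordance_parts <- function(risk, times, events) {
  n <- length(times)
  events <- as.integer(events)
  dt <- outer(times, times, "-")          # dt[i,j] = t_i - t_j
  ei <- matrix(events == 1L, n, n)        # row i: subject i had event
  first_i <- (dt < 0 & ei) | (dt == 0 & ei & t(!ei))
  dr <- outer(risk, risk, "-")            # dr[i,j] = r_i - r_j
  comparable <- first_i | t(first_i)
  diag(comparable) <- FALSE
  conc <- (first_i & dr > 0) | (t(first_i) & dr < 0)
  tied <- comparable & dr == 0
  list(comp_i = rowSums(comparable), conc_i = rowSums(conc),
       tied_i = rowSums(tied),
       comp = sum(comparable) / 2, conc = sum(conc) / 2,
       tied = sum(tied) / 2)
}

#' Harrell's concordance index
#'
#' Probability-of-concordance estimate for a risk score against censored
#' survival: over all comparable pairs (the pair member with the shorter
#' follow-up experienced the event; ties in time are comparable only when
#' exactly one member failed), the fraction in which the higher risk score
#' belongs to the earlier failure, counting tied risk scores as one half.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @inheritParams km_estimate
#' @return Concordance in \[0, 1\].
#' @examples
#' harrells_c(5:1, 1:5, rep(TRUE, 5))  # 1
#' @export
harrells_c <- function(risk, times, events) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  if (any(!is.finite(risk))) stop("risk scores must be finite", call. = FALSE)
  parts <- .concordance_parts(risk, times, events)
  if (parts$comp == 0)
    stop("no comparable pairs: concordance undefined", call. = FALSE)
  (parts$conc + 0.5 * parts$tied) / parts$comp
}

#' Compare two models' concordance on the same subjects
#'
#' Paired comparison of Harrell's C between two risk scores evaluated on
#' the same patients.  The standard error of the difference comes from a
#' paired leave-one-out jackknife: each subject is removed in turn, both
#' concordances are recomputed (by subtracting that subject's pair
#' contributions), and the jackknife variance of the per-subject
#' difference gives a normal-theory interval and two-sided p-value.
#'
#' @param risk_a,risk_b Risk score vectors on the same subjects.
#' @inheritParams km_estimate
#' @param conf_level Confidence level for the interval.
#' @return List of class `"c_comparison"`: `c_a`, `c_b`, `delta`
#'   (`c_a - c_b`), `delta_ci`, `se`, `p`, `n`.
#' @export
compare_c <- function(risk_a, risk_b, times, events, conf_level = 0.95) {
  if (length(risk_a) != length(risk_b))
    stop("risk vectors must describe the same subjects", call. = FALSE)
  stopifnot(length(risk_a) == length(times), length(times) == length(events))
  pa <- .concordance_parts(risk_a, times, events)
  pb <- .concordance_parts(risk_b, times, events)
  if (pa$comp == 0) stop("no comparable pairs", call. = FALSE)
  cfull <- function(p) (p$conc + 0.5 * p$tied) / p$comp
  cloo <- function(p) {
    num <- (p$conc - p$conc_i) + 0.5 * (p$tied - p$tied_i)
    den <- p$comp - p$comp_i
    ifelse(den > 0, num / den, NA_real_)
  }
  c_a <- cfull(pa); c_b <- cfull(pb)
  d_i <- cloo(pa) - cloo(pb)
  keep <- !is.na(d_i)
  m <- sum(keep)
  delta <- c_a - c_b
  se <- if (m > 1)
    sqrt((m - 1) / m * sum((d_i[keep] - mean(d_i[keep]))^2)) else NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (!is.na(se) && se > 0) 2 * pnorm(-abs(delta / se))
  else if (identical(delta, 0) || isTRUE(abs(delta) < .Machine$double.eps)) 1
  else NA_real_
  structure(list(c_a = c_a, c_b = c_b, delta = delta,
                 delta_ci = delta + c(-1, 1) * z * se, se = se, p = p,
                 n = length(times)),
            class = "c_comparison")
}

#' @export
print.c_comparison <- function(x, ...) {
  cat(sprintf(
    "Harrell's C: %.3f vs %.3f; delta %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
    x$c_a, x$c_b, x$delta, x$delta_ci[1], x$delta_ci[2], x$p))
  invisible(x)
}

#' Likelihood-ratio test for nested models
#'
#' @param loglik_full Log likelihood of the larger model.
#' @param loglik_reduced Log likelihood of the nested model.
#' @param df_diff Difference in number of parameters (>= 1).
#' @param tol Tolerance for a slightly negative log-likelihood difference
#'   due to numerical optimisation.
#' @return Two-sided p-value from the chi-square reference distribution.
#' @examples
#' lr_test(-100, -100 - 3.841 / 2, 1)  # 0.05
#' @export
lr_test <- function(loglik_full, loglik_reduced, df_diff, tol = 1e-8) {
  stopifnot(df_diff >= 1)
  dll <- loglik_full - loglik_reduced
  if (dll < -tol)
    stop("loglik_full < loglik_reduced: models do not look nested",
         call. = FALSE)
  pchisq(2 * max(dll, 0), df = df_diff, lower.tail = FALSE)
}

#' Dialysis-free survival by renal response
#'
#' Kaplan-Meier analysis of time to dialysis initiation among renally
#' involved patients not on dialysis at baseline.  Death before dialysis
#' is treated as independent censoring (a competing-risk treatment would
#' lower both curves; see the package vignette).  Reports the dialysis-free
#' probability at 60 months (5 years) for responders and non-responders
#' with a log-rank comparison.
#'
#' @param records Data frame with `dialysis_time` (months) and
#'   `dialysis_event` columns, restricted to renal-involved patients not
#'   on dialysis at baseline.
#' @param renal_response_flags Logical vector: achieved renal response at
#'   the landmark.
#' @param horizon Months at which the survival probability is reported
#'   (default 60).
#' @return List with per-group `km` (`"km_summary"`), `surv_at_horizon`
#'   (named vector, responder / non_responder), `logrank_p`,
#'   `n_per_group`, `no_events` flag.
#' @export
dialysis_free_survival <- function(records, renal_response_flags,
                                   horizon = 60) {
  if (nrow(records) == 0L)
    stop("no renal-involved patients supplied", call. = FALSE)
  stopifnot(nrow(records) == length(renal_response_flags))
  times <- records$dialysis_time
  events <- as.integer(records$dialysis_event)
  resp <- as.logical(renal_response_flags)
  s_at <- function(sel) {
    if (!any(sel)) return(NA_real_)
    fit <- survival::survfit(
      survival::Surv(times[sel], events[sel]) ~ 1)
    sm <- summary(fit, times = horizon, extend = TRUE)
    sm$surv
  }
  p <- if (length(unique(resp)) == 2L)
    logrank_test(times, events, resp)$p else NA_real_
  list(
    km = list(responder = if (any(resp)) km_estimate(times[resp], events[resp]),
              non_responder = if (any(!resp))
                km_estimate(times[!resp], events[!resp])),
    surv_at_horizon = c(responder = s_at(resp), non_responder = s_at(!resp)),
    horizon = horizon,
    logrank_p = p,
    n_per_group = c(responder = sum(resp), non_responder = sum(!resp)),
    no_events = sum(events) == 0L
  )
}
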