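test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  expect_true(km$median_reached)

  cens <- km_estimate(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$curve$surv == 1))
  expect_false(cens$median_reached)

  single <- km_estimate(5, TRUE)
  expect_equal(single$median, 5)

  # with censoring: 5 subjects, censor at 2
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 1))
  # S(1)=4/5; S(3)=4/5*2/3=8/15; S(4)=4/15; S(5)=0
  expect_equal(km2$curve$surv[km2$curve$time == 3], 8 / 15)
  expect_equal(km2$median, 4)  # first time S <= 0.5
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(3)
  times <- rexp(40, 0.1)
  km <- km_estimate(times, rep(TRUE, 40))
  emp <- vapply(km$curve$time, function(t) mean(times > t), numeric(1))
  expect_equal(km$curve$surv, emp)
})

test_that("log-rank test behaves at the null and under separation", {
  set.seed(5)
  d <- sim_two_group(500, 500, 0.02, 0.06)
  expect_lt(logrank_test(d$times, d$events, d$group)$p, 0.001)

  # label-permutation invariance
  lr1 <- logrank_test(d$times, d$events, d$group)
  lr2 <- logrank_test(d$times, d$events, 1 - d$group)
  expect_equal(lr1$statistic, lr2$statistic)
  expect_error(logrank_test(1:5, rep(1, 5), rep("a", 5)), "two groups")
})

test_that("log-rank statistic matches the observed-minus-expected oracle", {
  # 6 subjects, no ties, no censoring: brute-force over risk sets
  times <- c(1, 2, 3, 4, 5, 6)
  events <- rep(1, 6)
  group <- c(0, 1, 0, 1, 0, 1)
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- times >= t
    d <- sum(times == t)
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    e1 <- d * n1 / n
    d1 <- sum(times == t & group == 1)
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- o_minus_e^2 / v
  expect_equal(logrank_test(times, events, group)$statistic, oracle,
               tolerance = 1e-10)
})

test_that("log-rank p-values are approximately uniform under the null", {
  set.seed(17)
  ps <- replicate(500, {
    d <- sim_two_group(20, 20, 0.05, 0.05, cens_max = 60)
    logrank_test(d$times, d$events, d$group)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cox_binary matches a grid-search partial-likelihood oracle", {
  times <- c(2, 5, 7, 9)
  events <- c(1, 1, 1, 1)
  ind <- c(1, 0, 1, 0)
  # Efron = Breslow here (no ties); brute-force the partial likelihood
  pl <- function(beta) {
    ll <- 0
    for (i in order(times)) {
      risk <- times >= times[i]
      ll <- ll + beta * ind[i] - log(sum(exp(beta * ind[risk])))
    }
    ll
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_hat <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- cox_binary(times, events, ind)
  expect_equal(log(fit$hr), beta_hat, tolerance = 1e-3)
})

test_that("cox_binary is symmetric and flags monotone likelihoods", {
  set.seed(9)
  d <- sim_two_group(200, 200, 0.02, 0.05)
  f1 <- cox_binary(d$times, d$events, d$group)
  f2 <- cox_binary(d$times, d$events, 1 - d$group)
  expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-6)
  expect_false(f1$monotone)

  # no events in one arm
  t <- c(rexp(20, 0.1), rep(50, 20))
  e <- c(rep(1, 20), rep(0, 20))
  g <- rep(c(1, 0), each = 20)
  expect_true(suppressWarnings(cox_binary(t, e, g))$monotone)
})

test_that("null Cox coverage is near nominal", {
  set.seed(12)
  covered <- replicate(100, {
    d <- sim_two_group(60, 60, 0.03, 0.03)
    ci <- cox_binary(d$times, d$events, d$group)$ci
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gte(mean(covered), 0.85)
})

test_that("Harrell's C handles perfect, constant and censored orderings", {
  expect_equal(harrells_c(5:1, 1:5, rep(TRUE, 5)), 1)
  expect_equal(harrells_c(rep(2, 5), 1:5, rep(TRUE, 5)), 0.5)
  # n = 6 with one censored subject: exhaustive oracle
  set.seed(21)
  risk <- rnorm(6); times <- rexp(6); events <- c(1, 1, 0, 1, 1, 1)
  expect_equal(harrells_c(risk, times, events),
               brute_force_c(risk, times, events))
  expect_error(harrells_c(c(1, 2), c(3, 1), c(0, 0)), "comparable")
})

test_that("Harrell's C equals the exhaustive pairwise oracle with ties", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    risk <- sample(1:4, n, replace = TRUE)           # risk ties
    times <- sample(1:10, n, replace = TRUE)         # time ties
    events <- as.integer(runif(n) < 0.7)
    if (sum(events) == 0) next
    got <- tryCatch(harrells_c(risk, times, events), error = function(e) NA)
    want <- tryCatch(brute_force_c(risk, times, events),
                     error = function(e) NA)
    if (is.na(want) || is.nan(want)) next
    expect_equal(got, want, info = sprintf("instance %d (n=%d)", i, n))
  }
})

test_that("compare_c is exactly zero on identical models and detects signal", {
  set.seed(41)
  times <- rexp(60, 0.05); events <- as.integer(runif(60) < 0.7)
  risk <- rnorm(60)
  same <- compare_c(risk, risk, times, events)
  expect_identical(same$delta, 0)
  expect_equal(same$p, 1)

  # predictive vs noise: delta positive with CI excluding 0 (most seeds)
  hits <- replicate(20, {
    t <- rexp(200, 0.05); e <- as.integer(runif(200) < 0.8)
    good <- -t + rnorm(200, sd = 0.1)  # near-perfect risk ordering
    noise <- rnorm(200)
    cmp <- compare_c(good, noise, t, e)
    cmp$delta > 0 && cmp$delta_ci[1] > 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("jackknife SE matches direct leave-one-out recomputation", {
  set.seed(51)
  n <- 30
  times <- rexp(n, 0.1); events <- as.integer(runif(n) < 0.7)
  risk_a <- -times + rnorm(n); risk_b <- rnorm(n)
  cmp <- compare_c(risk_a, risk_b, times, events)
  d_i <- vapply(seq_len(n), function(i) {
    harrells_c(risk_a[-i], times[-i], events[-i]) -
      harrells_c(risk_b[-i], times[-i], events[-i])
  }, numeric(1))
  se_direct <- sqrt((n - 1) / n * sum((d_i - mean(d_i))^2))
  expect_equal(cmp$se, se_direct, tolerance = 1e-12)
})

test_that("likelihood-ratio test matches the chi-square reference", {
  expect_equal(lr_test(-10, -10, 1), 1)
  expect_equal(lr_test(-100, -100 - 3.841 / 2, 1), 0.05, tolerance = 1e-3)
  expect_equal(lr_test(-50, -55, 2), pchisq(10, 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(lr_test(-20, -10, 1), "nested")
})

test_that("dialysis-free survival reports per-group 5-year probabilities", {
  set.seed(61)
  n <- 2000
  resp <- rep(c(TRUE, FALSE), length.out = n)
  rate <- ifelse(resp, -log(0.88) / 60, -log(0.65) / 60)
  t_d <- rexp(n, rate)
  cens <- runif(n, 40, 120)
  rec <- data.frame(dialysis_time = pmin(t_d, cens),
                    dialysis_event = t_d <= cens)
  dfs <- dialysis_free_survival(rec, resp)
  # KM under independent censoring recovers this draw's uncensored truth
  expect_equal(unname(dfs$surv_at_horizon["responder"]),
               mean(t_d[resp] > 60), tolerance = 0.02)
  expect_equal(unname(dfs$surv_at_horizon["non_responder"]),
               mean(t_d[!resp] > 60), tolerance = 0.02)
  expect_gt(dfs$surv_at_horizon[["responder"]],
            dfs$surv_at_horizon[["non_responder"]])
  expect_lt(dfs$logrank_p, 0.05)

  expect_error(dialysis_free_survival(rec[0, ], logical(0)), "no renal")
  none <- dialysis_free_survival(
    data.frame(dialysis_time = rep(60, 10), dialysis_event = rep(FALSE, 10)),
    rep(TRUE, 10))
  expect_true(none$no_events)
  expect_equal(unname(none$surv_at_horizon["responder"]), 1)
})
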