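# Log-normal parameters from a printed median and interquartile range.
.lnorm_params <- function(spec) {
  meanlog <- log(spec[["median"]])
  sdlog <- (log(spec[["q3"]]) - log(spec[["q1"]])) / (2 * qnorm(0.75))
  c(meanlog = meanlog, sdlog = sdlog)
}

.norm_params <- function(spec) {
  c(mean = spec[["median"]],
    sd = (spec[["q3"]] - spec[["q1"]]) / (2 * qnorm(0.75)))
}

# Raw independent-draw involvement probabilities whose conditional
# marginals (given >= 1 involved organ) equal the targets.  Fixed point of
# p = target * P(>=1 | p).
.solve_involvement <- function(target) {
  p <- target
  for (i in 1:200) {
    p_any <- 1 - prod(1 - p)
    p_new <- target * p_any
    if (max(abs(p_new - p)) < 1e-12) break
    p <- p_new
  }
  if (any(p <= 0 | p >= 1))
    stop("involvement marginals are infeasible", call. = FALSE)
  p
}

# Distribution of the number of evaluable major organs for a random
# patient (conditioned on >= 1 involved), under independent involvement,
# the cardiac NT-proBNP evaluability floor, and baseline dialysis.
.evaluable_count_dist <- function(config) {
  raw <- .solve_involvement(config$organ_involvement_probs)
  lp <- .lnorm_params(config$baseline_distributions$ntprobnp)
  p_heart_eval <- 1 - stats::plnorm(config$thresholds$cardiac_eval_floor,
                                    lp["meanlog"], lp["sdlog"])
  p_eval <- c(heart = unname(p_heart_eval),
              kidney = 1 - config$dialysis_prob,
              liver = 1)
  pk <- numeric(4)  # P(K = 0..3)
  for (h in 0:1) for (k in 0:1) for (l in 0:1) {
    inv <- c(h, k, l)
    if (sum(inv) == 0) next
    p_pattern <- prod(ifelse(inv == 1, raw, 1 - raw))
    # K | pattern: sum of independent evaluability Bernoullis
    dist <- 1
    for (o in 1:3) if (inv[o] == 1)
      dist <- convolve(dist, rev(c(1 - p_eval[o], p_eval[o])), type = "open")
    pk[seq_along(dist)] <- pk[seq_along(dist)] + p_pattern * dist
  }
  pk <- pk / sum(pk)
  pk
}

#' Solve per-organ response probabilities from target AOR rates
#'
#' Under the generator's structure (organ responses conditionally
#' independent given hematologic depth, common per-organ probability `q`),
#' the all-organ-response rate among patients with at least one evaluable
#' organ is `E[q^K | K >= 1]` where `K` is the number of evaluable major
#' organs.  This inverts that relation: given the target AOR rate for each
#' hematologic depth it returns the per-organ probability reproducing it
#' in expectation.
#'
#' @param config A [simulation_config()] (its involvement marginals,
#'   NT-proBNP distribution and dialysis rate determine the distribution
#'   of `K`).
#' @param aor_targets Named vector of AOR rates by depth
#'   (`CR`, `VGPR`, `PR`, `NR`).
#' @return Named vector of per-organ response probabilities.
#' @export
solve_organ_response_probs <- function(config, aor_targets) {
  pk <- .evaluable_count_dist(config)
  cond <- pk[2:4] / sum(pk[2:4])  # P(K = k | K >= 1), k = 1..3
  vapply(aor_targets, function(target) {
    if (target <= 0) return(0)
    f <- function(q) sum(cond * q^(1:3)) - target
    stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  }, numeric(1))
}

#' Synthetic cohort simulation configuration
#'
#' Everything the generator needs: cohort size, organ-involvement
#' marginals, hematologic response mix, per-organ response probabilities
#' by hematologic depth, baseline biomarker distributions (log-normal for
#' right-skewed markers, parameterised by printed median and quartiles;
#' normal for age and eGFR), dialysis prevalence, and the survival model
#' (exponential or Weibull baseline hazard with a CHOR-group-2 hazard
#' multiplier, uniform administrative censoring, and a renal-response
#' dependent dialysis hazard calibrated to 5-year dialysis-free
#' probabilities).
#'
#' Use [mayo_default_config()] or [pavia_default_config()] for ready-made
#' configurations encoding the two referral cohorts' printed marginals.
#'
#' @param n_patients Cohort size.
#' @param seed Default random seed for [simulate_cohort()].
#' @param landmark_months Response landmark (months).
#' @param organ_involvement_probs Named vector (`heart`, `kidney`,
#'   `liver`): target marginal involvement rates *after* conditioning on
#'   at least one involved major organ.
#' @param low_dflc_prob Fraction with baseline dFLC < 5 mg/dL.
#' @param hr_category_probs Named vector (`CR`, `VGPR`, `PR`, `NR`)
#'   summing to 1: hematologic mix among standard-pathway patients.
#' @param low_dflc_cr_prob CR rate among low-dFLC patients.
#' @param aor_target_given_hr Named vector: target AOR rate by depth, used
#'   to solve `organ_response_given_hr` when the latter is NULL.
#' @param organ_response_given_hr Named vector: per-organ response
#'   probability by depth (`CR`, `VGPR`, `PR`, `NR`); low-dFLC non-CR
#'   patients use the `VGPR` value.  Solved from `aor_target_given_hr`
#'   via [solve_organ_response_probs()] when NULL.
#' @param baseline_distributions List of per-marker specs: `dflc`,
#'   `ntprobnp`, `proteinuria`, `alp` and optionally `troponin_t` as
#'   `c(median=, q1=, q3=)` log-normal specs; `egfr` and `age` as normal
#'   specs; `male_prob` a scalar.
#' @param dialysis_prob Fraction of kidney-involved patients on dialysis
#'   at baseline.
#' @param survival List: `dist` (`"exponential"` or `"weibull"`),
#'   `base_rate` (events/month; Weibull scale is `1/base_rate`), `shape`
#'   (Weibull only), `group2_multiplier` (hazard ratio of CHOR group 2 vs
#'   group 1), `censor_max` (months; administrative censoring uniform on
#'   \[landmark, censor_max\]).
#' @param dialysis_model List: `dialysis_free_5yr` named vector
#'   (`responder`, `non_responder`) of 60-month dialysis-free
#'   probabilities, converted internally to exponential hazards.
#' @param thresholds [response_thresholds()] the generated biomarkers are
#'   made consistent with.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_patients,
                              seed = 1L,
                              landmark_months = 6,
                              organ_involvement_probs,
                              low_dflc_prob,
                              hr_category_probs,
                              low_dflc_cr_prob,
                              aor_target_given_hr,
                              organ_response_given_hr = NULL,
                              baseline_distributions,
                              dialysis_prob,
                              survival,
                              dialysis_model,
                              thresholds = response_thresholds()) {
  config <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    landmark_months = landmark_months,
    organ_involvement_probs = organ_involvement_probs,
    low_dflc_prob = low_dflc_prob,
    hr_category_probs = hr_category_probs,
    low_dflc_cr_prob = low_dflc_cr_prob,
    aor_target_given_hr = aor_target_given_hr,
    organ_response_given_hr = organ_response_given_hr,
    baseline_distributions = baseline_distributions,
    dialysis_prob = dialysis_prob,
    survival = survival,
    dialysis_model = dialysis_model,
    thresholds = thresholds)
  if (is.null(config$organ_response_given_hr))
    config$organ_response_given_hr <-
      solve_organ_response_probs(config, aor_target_given_hr)
  validate_simulation_config(config)
  structure(config, class = "simulation_config")
}

#' Validate a simulation configuration
#'
#' Checks probability ranges, that the hematologic mix sums to one, and
#' that hazard parameters are positive.  Problems are reported together.
#'
#' @param config A configuration list.
#' @return `config`, invisibly, or an error enumerating every violation.
#' @export
validate_simulation_config <- function(config) {
  probs01 <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 1)
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)
  if (!isTRUE(config$n_patients >= 1)) add("n_patients must be >= 1")
  if (!probs01(config$organ_involvement_probs) ||
      !setequal(names(config$organ_involvement_probs),
                c("heart", "kidney", "liver")))
    add("organ_involvement_probs must be heart/kidney/liver in [0,1]")
  if (!probs01(config$low_dflc_prob)) add("low_dflc_prob must be in [0,1]")
  if (!probs01(config$hr_category_probs) ||
      abs(sum(config$hr_category_probs) - 1) > 1e-8 ||
      !setequal(names(config$hr_category_probs),
                c("CR", "VGPR", "PR", "NR")))
    add("hr_category_probs must be CR/VGPR/PR/NR summing to 1")
  if (!probs01(config$low_dflc_cr_prob)) add("low_dflc_cr_prob in [0,1]")
  if (!probs01(config$organ_response_given_hr))
    add("organ_response_given_hr must be probabilities")
  if (!probs01(config$dialysis_prob)) add("dialysis_prob in [0,1]")
  sv <- config$survival
  if (!sv$dist %in% c("exponential", "weibull")) add("unknown survival dist")
  if (!isTRUE(sv$base_rate > 0)) add("base_rate must be > 0")
  if (!isTRUE(sv$group2_multiplier > 0)) add("group2_multiplier must be > 0")
  if (!isTRUE(sv$censor_max > config$landmark_months))
    add("censor_max must exceed the landmark")
  if (sv$dist == "weibull" && !isTRUE(sv$shape > 0))
    add("weibull shape must be > 0")
  if (!probs01(config$dialysis_model$dialysis_free_5yr))
    add("dialysis_free_5yr must be probabilities")
  # partial response needs headroom: it is attainable only when baseline
  # dFLC >= vgpr_dflc / (1 - pr_reduction); the category mix must leave
  # room to place all PR mass there (see generate_responses)
  w <- .pr_infeasible_weight(config)
  if (config$hr_category_probs[["PR"]] > 0 &&
      w > 1 - config$hr_category_probs[["PR"]])
    add("PR rate incompatible with the baseline dFLC distribution")
  if (length(issues))
    stop("invalid simulation config:\n  ",
         paste(issues, collapse = "\n  "), call. = FALSE)
  invisible(config)
}

# P(baseline dFLC below the PR-attainability bound | standard pathway).
.pr_infeasible_weight <- function(config) {
  th <- config$thresholds
  bound <- th$vgpr_dflc / (1 - th$pr_reduction)
  lp <- .lnorm_params(config$baseline_distributions$dflc)
  lo <- stats::plnorm(th$low_dflc_cutoff, lp["meanlog"], lp["sdlog"])
  hi <- stats::plnorm(bound, lp["meanlog"], lp["sdlog"])
  unname(max(0, (hi - lo) / (1 - lo)))
}

#' @rdname simulation_config
#' @param n_patients Cohort size (defaults to the source cohort's).
#' @param seed Default seed.
#' @export
mayo_default_config <- function(n_patients = 473, seed = 1L) {
  simulation_config(
    n_patients = n_patients, seed = seed, landmark_months = 6,
    organ_involvement_probs = c(heart = 0.70, kidney = 0.70, liver = 0.14),
    low_dflc_prob = 63 / 473,
    hr_category_probs = c(CR = 101, VGPR = 144, PR = 99, NR = 66) / 410,
    low_dflc_cr_prob = 18 / 63,
    aor_target_given_hr = c(CR = 45 / 119, VGPR = 57 / 189, PR = 16 / 99,
                            NR = 7 / 66),
    baseline_distributions = list(
      dflc = c(median = 19, q1 = 8, q3 = 55),
      ntprobnp = c(median = 1625, q1 = 327, q3 = 4296),
      proteinuria = c(median = 2629, q1 = 375, q3 = 7008),
      alp = c(median = 86, q1 = 69, q3 = 118),
      troponin_t = c(median = 0.02, q1 = 0.01, q3 = 0.05),
      egfr = c(median = 65, q1 = 48, q3 = 82),
      age = c(median = 63, q1 = 56, q3 = 69),
      male_prob = 0.65),
    dialysis_prob = 14 / 330,
    survival = list(dist = "exponential",
                    base_rate = log(2) / (34 * 3.4),
                    group2_multiplier = 3.4,
                    censor_max = 120),
    dialysis_model = list(
      dialysis_free_5yr = c(responder = 0.88, non_responder = 0.65)))
}

#' @rdname simulation_config
#' @export
pavia_default_config <- function(n_patients = 575, seed = 1L) {
  simulation_config(
    n_patients = n_patients, seed = seed, landmark_months = 6,
    organ_involvement_probs = c(heart = 0.79, kidney = 0.69, liver = 0.11),
    low_dflc_prob = 39 / 575,
    hr_category_probs = c(CR = 74, VGPR = 176, PR = 105, NR = 181) / 536,
    low_dflc_cr_prob = 1,
    aor_target_given_hr = c(CR = 40 / 113, VGPR = 46 / 176, PR = 22 / 105,
                            NR = 0.05),
    baseline_distributions = list(
      dflc = c(median = 19, q1 = 9, q3 = 52),
      ntprobnp = c(median = 2215, q1 = 704, q3 = 5578),
      proteinuria = c(median = 2561, q1 = 392, q3 = 6590),
      alp = c(median = 149, q1 = 88, q3 = 217),
      troponin_t = NULL,
      egfr = c(median = 69, q1 = 49, q3 = 87),
      age = c(median = 64, q1 = 56, q3 = 70),
      male_prob = 0.58),
    dialysis_prob = 9 / 399,
    survival = list(dist = "exponential",
                    base_rate = log(2) / 87,
                    group2_multiplier = 2.8,
                    censor_max = 120),
    dialysis_model = list(
      dialysis_free_5yr = c(responder = 0.88, non_responder = 0.65)))
}

# Truncated draws via the inverse-CDF on a probability sub-interval.
.rlnorm_trunc <- function(n, lp, lower = 0, upper = Inf) {
  lo <- stats::plnorm(lower, lp["meanlog"], lp["sdlog"])
  hi <- stats::plnorm(upper, lp["meanlog"], lp["sdlog"])
  stats::qlnorm(runif(n, lo, hi), lp["meanlog"], lp["sdlog"])
}

#' Generate baseline characteristics
#'
#' Samples organ involvement (conditioned on at least one involved major
#' organ, with raw draw probabilities adjusted so that the *conditional*
#' marginals equal the configured ones), baseline biomarkers from the
#' configured distributions, the low-dFLC flag (baseline dFLC is drawn
#' from the matching truncated log-normal), and baseline dialysis among
#' kidney-involved patients.
#'
#' @param config A [simulation_config()].
#' @param seed Seed set before drawing; `NULL` continues the current RNG
#'   stream (as [simulate_cohort()] does).
#' @return A baseline cohort data frame, one row per patient.
#' @export
generate_baseline <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  bd <- config$baseline_distributions
  raw <- .solve_involvement(config$organ_involvement_probs)

  patterns <- expand.grid(heart = 0:1, kidney = 0:1, liver = 0:1)
  patterns <- patterns[rowSums(patterns) > 0, ]
  pp <- apply(patterns, 1, function(inv)
    prod(ifelse(inv == 1, raw, 1 - raw)))
  idx <- sample.int(nrow(patterns), n, replace = TRUE, prob = pp)

  low <- runif(n) < config$low_dflc_prob
  lp_dflc <- .lnorm_params(bd$dflc)
  cutoff <- config$thresholds$low_dflc_cutoff
  dflc <- numeric(n)
  dflc[low] <- .rlnorm_trunc(sum(low), lp_dflc, upper = cutoff)
  dflc[!low] <- .rlnorm_trunc(sum(!low), lp_dflc, lower = cutoff)

  age_p <- .norm_params(bd$age)
  egfr_p <- .norm_params(bd$egfr)
  kidney <- patterns$kidney[idx] == 1
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = pmin(pmax(rnorm(n, age_p["mean"], age_p["sd"]), 18), 95),
    sex_male = runif(n) < bd$male_prob,
    heart_involved = patterns$heart[idx] == 1,
    kidney_involved = kidney,
    liver_involved = patterns$liver[idx] == 1,
    on_dialysis_at_baseline = kidney & runif(n) < config$dialysis_prob,
    baseline_dflc = dflc,
    baseline_ifix_negative = FALSE,
    baseline_flc_ratio_normal = FALSE,
    baseline_ntprobnp = .rlnorm_trunc(n, .lnorm_params(bd$ntprobnp)),
    baseline_troponin_t = if (is.null(bd$troponin_t)) NA_real_ else
      .rlnorm_trunc(n, .lnorm_params(bd$troponin_t)),
    baseline_proteinuria = .rlnorm_trunc(n, .lnorm_params(bd$proteinuria)),
    baseline_egfr = pmax(rnorm(n, egfr_p["mean"], egfr_p["sd"]), 5),
    baseline_alp = .rlnorm_trunc(n, .lnorm_params(bd$alp)),
    landmark_months = config$landmark_months,
    stringsAsFactors = FALSE)
  out
}

#' Generate landmark responses and consistent biomarkers
#'
#' Draws each patient's latent hematologic category (low-dFLC patients by
#' the CR-only pathway), then an independent response Bernoulli per
#' involved-and-evaluable organ with a probability depending on
#' hematologic depth, and finally emits landmark biomarker values lying
#' inside (responders) or outside (non-responders) the corresponding
#' response region, so that the classifiers reproduce the latent statuses
#' exactly.
#'
#' Partial response is attainable only when baseline dFLC is at least
#' 8 mg/dL (below that, any 50% reduction already lands under the 4 mg/dL
#' VGPR threshold), so the category draw is stratified on that bound with
#' weights chosen to keep the configured marginal mix exact.
#'
#' @param baseline Output of [generate_baseline()].
#' @inheritParams generate_baseline
#' @return `baseline` with landmark biomarker columns and latent
#'   `latent_hr_category`, `latent_cardiac`, `latent_renal`,
#'   `latent_liver` columns appended.
#' @export
generate_responses <- function(baseline, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(baseline)
  th <- config$thresholds
  b <- baseline$baseline_dflc
  low <- b < th$low_dflc_cutoff

  cat <- rep(NA_character_, n)
  ifix <- logical(n); ratio <- logical(n)
  land_dflc <- numeric(n)

  # low-dFLC pathway: CR or not, scored elsewhere
  cr_low <- low & runif(n) < config$low_dflc_cr_prob
  cat[low] <- ifelse(cr_low[low], "CR", "NR")
  ifix[cr_low] <- TRUE; ratio[cr_low] <- TRUE
  land_dflc[low] <- runif(sum(low), 0, b[low])

  # standard pathway, PR-attainability stratification
  pr_bound <- th$vgpr_dflc / (1 - th$pr_reduction)
  w <- .pr_infeasible_weight(config)
  p <- config$hr_category_probs
  p_pr <- p[["PR"]]
  below <- !low & b < pr_bound
  above <- !low & b >= pr_bound
  probs_below <- c(p[["CR"]], p[["VGPR"]], 0, p[["NR"]]) / (1 - p_pr)
  probs_above <- if (w >= 1) probs_below else
    c(p[["CR"]], p[["VGPR"]], 0, p[["NR"]]) *
      (1 - p_pr - w) / ((1 - p_pr) * (1 - w)) +
    c(0, 0, p_pr / (1 - w), 0)
  lv <- c("CR", "VGPR", "PR", "NR")
  if (any(below))
    cat[below] <- sample(lv, sum(below), replace = TRUE, prob = probs_below)
  if (any(above))
    cat[above] <- sample(lv, sum(above), replace = TRUE, prob = probs_above)

  std <- !low
  is_cr <- std & cat == "CR"
  ifix[is_cr] <- TRUE; ratio[is_cr] <- TRUE
  land_dflc[is_cr] <- runif(sum(is_cr), 0, th$vgpr_dflc)
  is_v <- std & cat == "VGPR"
  land_dflc[is_v] <- runif(sum(is_v), 0, th$vgpr_dflc)
  is_p <- std & cat == "PR"
  land_dflc[is_p] <- runif(sum(is_p), th$vgpr_dflc,
                           (1 - th$pr_reduction) * b[is_p])
  is_n <- std & cat == "NR"
  land_dflc[is_n] <- runif(sum(is_n),
                           pmax(th$vgpr_dflc, (1 - th$pr_reduction) * b[is_n]),
                           1.2 * b[is_n])

  # organ responses: depth-dependent Bernoulli per evaluable organ
  depth <- cat
  depth[low & cat != "CR"] <- "VGPR"  # low-dFLC non-CR tracks VGPR
  q <- config$organ_response_given_hr[depth]

  heart_eval <- baseline$heart_involved &
    baseline$baseline_ntprobnp >= th$cardiac_eval_floor
  kidney_eval <- baseline$kidney_involved & !baseline$on_dialysis_at_baseline
  liver_eval <- baseline$liver_involved
  draw_status <- function(eval) ifelse(!eval, "NOT_EVALUABLE",
                                ifelse(runif(n) < q, "RESPONSE",
                                       "NO_RESPONSE"))
  cardiac <- draw_status(heart_eval)
  renal <- draw_status(kidney_eval)
  liver <- draw_status(liver_eval)

  # landmark NT-proBNP: responders inside the joint (>30%, >300 pg/mL)
  # region, everyone else with a change failing the relative clause
  bn <- baseline$baseline_ntprobnp
  f <- runif(n, -0.2, th$cardiac_rel_decrease)
  ri <- cardiac == "RESPONSE"
  lo_f <- pmax(th$cardiac_rel_decrease, th$cardiac_abs_decrease / bn[ri])
  f[ri] <- lo_f + runif(sum(ri)) * (0.8 - lo_f)
  land_ntprobnp <- bn * (1 - f)

  # landmark proteinuria / eGFR
  bp <- baseline$baseline_proteinuria
  be <- baseline$baseline_egfr
  u_p <- runif(n, -0.3, th$renal_prot_reduction - 0.05)
  land_prot <- pmax(th$renal_prot_floor, bp * (1 - u_p))
  u_e <- runif(n, -0.1, th$renal_egfr_decline - 0.05)
  land_egfr <- be * (1 - u_e)
  ri <- renal == "RESPONSE"
  land_prot[ri] <- bp[ri] * (1 - runif(sum(ri), th$renal_prot_reduction, 0.9))
  ni <- renal == "NO_RESPONSE" & runif(n) < 0.5
  land_egfr[ni] <- be[ni] * (1 - runif(sum(ni), th$renal_egfr_decline + 0.05,
                                       0.5))

  # landmark alkaline phosphatase
  ba <- baseline$baseline_alp
  u_a <- runif(n, 1 - th$liver_alp_reduction + 0.05, 1.3)
  ri <- liver == "RESPONSE"
  u_a[ri] <- runif(sum(ri), 0.2, 1 - th$liver_alp_reduction)
  land_alp <- ba * u_a

  baseline$landmark_dflc <- land_dflc
  baseline$landmark_ifix_negative <- ifix
  baseline$landmark_flc_ratio_normal <- ratio
  baseline$landmark_ntprobnp <- land_ntprobnp
  baseline$landmark_proteinuria <- land_prot
  baseline$landmark_egfr <- land_egfr
  baseline$landmark_alp <- land_alp
  baseline$latent_hr_category <- cat
  baseline$latent_cardiac <- cardiac
  baseline$latent_renal <- renal
  baseline$latent_liver <- liver
  baseline
}

# Quantile of the configured event-time distribution conditional on
# exceeding the landmark (left truncation).
.rsurv_trunc <- function(u, rate, config) {
  sv <- config$survival
  L <- config$landmark_months
  if (sv$dist == "exponential") {
    L + stats::qexp(u, rate)  # memoryless
  } else {
    scale <- (1 / rate)^(1 / sv$shape)
    pL <- stats::pweibull(L, sv$shape, scale)
    stats::qweibull(pL + u * (1 - pL), sv$shape, scale)
  }
}

#' Generate survival and dialysis outcomes
#'
#' Event times come from the configured baseline hazard multiplied by the
#' CHOR-group hazard ratio (group 1: 1; group 2: `group2_multiplier`;
#' unscored patients use the baseline hazard), left-truncated at the
#' landmark (the analysis cohort is alive at response assessment), with
#' administrative censoring uniform on \[landmark, `censor_max`\].
#' Kidney-involved patients not on baseline dialysis additionally get a
#' time to dialysis initiation from an exponential hazard calibrated to
#' the configured 5-year dialysis-free probability of their latent renal
#' response status; death and administrative censoring end dialysis
#' follow-up.
#'
#' @param scored A scored cohort (needs `chor_group`; see
#'   [score_cohort()]).
#' @inheritParams generate_baseline
#' @return `scored` with `os_time`, `os_event`, `dialysis_time`,
#'   `dialysis_event` appended.
#' @export
generate_survival <- function(scored, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scored$chor_group))
    stop("cohort must be scored (chor_group missing); see score_cohort()",
         call. = FALSE)
  n <- nrow(scored)
  sv <- config$survival
  mult <- ifelse(!is.na(scored$chor_group) & scored$chor_group == "GROUP2",
                 sv$group2_multiplier, 1)
  t_death <- .rsurv_trunc(runif(n), sv$base_rate * mult, config)
  cens <- runif(n, config$landmark_months, sv$censor_max)
  scored$os_time <- pmin(t_death, cens)
  scored$os_event <- t_death <= cens

  s5 <- config$dialysis_model$dialysis_free_5yr
  rate_d <- -log(s5) / 60
  eligible <- scored$kidney_involved & !scored$on_dialysis_at_baseline
  t_dial <- rep(Inf, n)
  resp <- eligible & scored$latent_renal == "RESPONSE"
  nonresp <- eligible & scored$latent_renal == "NO_RESPONSE"
  t_dial[resp] <- rexp(sum(resp), rate_d[["responder"]])
  t_dial[nonresp] <- rexp(sum(nonresp), rate_d[["non_responder"]])
  stop_t <- pmin(t_death, cens)
  scored$dialysis_time <- ifelse(eligible, pmin(t_dial, stop_t), NA_real_)
  scored$dialysis_event <- ifelse(eligible, t_dial <= stop_t, NA)
  scored
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_baseline()], [generate_responses()], the classifiers
#' ([assess_cohort()]), composite scoring ([score_cohort()]) and
#' [generate_survival()] under a single seed.
#'
#' @inheritParams generate_baseline
#' @return A fully populated cohort data frame with latent truth, assessed
#'   responses, CHOR scores and survival outcomes; the configuration is
#'   attached as attribute `"config"`.
#' @examples
#' cohort <- simulate_cohort(mayo_default_config(n_patients = 200), seed = 7)
#' table(cohort$chor_group, useNA = "ifany")
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  set.seed(seed)
  cohort <- generate_baseline(config, seed = NULL)
  cohort <- generate_responses(cohort, config, seed = NULL)
  cohort <- assess_cohort(cohort, config$thresholds)
  cohort <- score_cohort(cohort)
  cohort <- generate_survival(cohort, config, seed = NULL)
  attr(cohort, "config") <- config
  attr(cohort, "seed") <- seed
  cohort
}
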