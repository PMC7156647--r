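#' Combine per-organ statuses into AOR / MOR / NOR
#'
#' Major organs are heart, kidney and liver.  All organ response (AOR) is
#' response in every involved-and-evaluable organ; no organ response (NOR)
#' is response in none; mixed organ response (MOR) is anything in between.
#' A patient with no evaluable organ is `NOT_EVALUABLE` and must be
#' excluded from composite scoring.
#'
#' @param assessment A `"chor_assessment"` from [assess_patient()], or any
#'   list with `cardiac`, `renal`, `liver` statuses.
#' @return A list of class `"combined_or"` with `category` (`"AOR"`,
#'   `"MOR"`, `"NOR"` or `"NOT_EVALUABLE"`), `n_evaluable`, `n_responding`.
#' @examples
#' a <- list(cardiac = "RESPONSE", renal = "RESPONSE", liver = "NOT_EVALUABLE")
#' combine_organ_responses(a)$category  # "AOR"
#' @export
combine_organ_responses <- function(assessment) {
  st <- c(assessment$cardiac, assessment$renal, assessment$liver)
  if (length(st) != 3L || any(!st %in% .organ_levels))
    stop("assessment must carry cardiac, renal and liver statuses",
         call. = FALSE)
  n_eval <- sum(st != "NOT_EVALUABLE")
  n_resp <- sum(st == "RESPONSE")
  category <- if (n_eval == 0L) "NOT_EVALUABLE"
  else if (n_resp == n_eval) "AOR"
  else if (n_resp == 0L) "NOR"
  else "MOR"
  structure(list(category = category, n_evaluable = n_eval,
                 n_responding = n_resp), class = "combined_or")
}

#' Hematologic points for the CHOR score
#'
#' Standard pathway: CR 0, VGPR 1, PR 2, NR (or progression) 3.  Patients
#' on the low-dFLC pathway (baseline dFLC < 5 mg/dL) score 0 for CR and 1
#' otherwise, because their survival without CR tracks that of VGPR
#' patients.
#'
#' @param cat An `"hr_category"` from [classify_hematologic()], or a list
#'   with `category` and `low_dflc_pathway`.
#' @return Integer 0-3.
#' @export
hematologic_points <- function(cat) {
  category <- match.arg(cat$category, .hr_levels)
  if (isTRUE(cat$low_dflc_pathway))
    return(if (category == "CR") 0L else 1L)
  c(CR = 0L, VGPR = 1L, PR = 2L, NR = 3L)[[category]]
}

#' Organ points for the CHOR score
#'
#' AOR 0, MOR 1, NOR 2.  A `NOT_EVALUABLE` combined organ response cannot
#' be scored; such patients are excluded upstream.
#'
#' @param combined A `"combined_or"` from [combine_organ_responses()].
#' @return Integer 0-2.
#' @export
organ_points <- function(combined) {
  category <- match.arg(combined$category,
                        c("AOR", "MOR", "NOR", "NOT_EVALUABLE"))
  if (category == "NOT_EVALUABLE")
    stop("combined organ response is not evaluable; ",
         "patient cannot receive a CHOR score", call. = FALSE)
  c(AOR = 0L, MOR = 1L, NOR = 2L)[[category]]
}

#' Composite hematologic + organ response (CHOR) score
#'
#' Adds the hematologic points (0-3) and organ points (0-2) for a total of
#' 0-5 and assigns the published two-group partition: group 1 is scores
#' 0-3, group 2 is scores 4-5.
#'
#' @param assessment A `"chor_assessment"` from [assess_patient()].
#' @param cut_after Highest score included in group 1 (default 3, the
#'   published partition; see [build_grouping()] to re-derive it).
#' @return A list of class `"chor_result"` with `hr_points`, `or_points`,
#'   `total`, `group` (`"GROUP1"` or `"GROUP2"`) and `combined_or`.
#' @examples
#' rec <- list(baseline_dflc = 19, landmark_ifix_negative = TRUE,
#'             landmark_flc_ratio_normal = TRUE, landmark_dflc = 1,
#'             heart_involved = TRUE, baseline_ntprobnp = 2000,
#'             landmark_ntprobnp = 1300, kidney_involved = FALSE,
#'             liver_involved = FALSE, landmark_months = 6)
#' chor_score(assess_patient(rec))$total  # 0
#' @export
chor_score <- function(assessment, cut_after = 3L) {
  stopifnot(cut_after %in% 0:4)
  combined <- combine_organ_responses(assessment)
  hr_pts <- hematologic_points(assessment$hematologic)
  or_pts <- organ_points(combined)
  total <- hr_pts + or_pts
  structure(list(hr_points = hr_pts, or_points = or_pts, total = total,
                 group = if (total <= cut_after) "GROUP1" else "GROUP2",
                 combined_or = combined$category),
            class = "chor_result")
}

#' @export
print.chor_result <- function(x, ...) {
  cat(sprintf("CHOR score %d (HR %d + OR %d, combined OR %s) -> %s\n",
              x$total, x$hr_points, x$or_points, x$combined_or, x$group))
  invisible(x)
}

#' Score an assessed cohort
#'
#' Applies [combine_organ_responses()] and [chor_score()] row-wise to the
#' output of [assess_cohort()].  Patients whose hematologic category or
#' combined organ response is not evaluable get NA scores together with an
#' `exclusion_reason`, mirroring the consort accounting of a landmark
#' analysis.
#'
#' @param assessed Output of [assess_cohort()].
#' @inheritParams chor_score
#' @return `assessed` with columns `combined_or`, `n_evaluable_organs`,
#'   `n_responding_organs`, `hr_points`, `or_points`, `chor_total`,
#'   `chor_group`, `exclusion_reason` appended.
#' @export
score_cohort <- function(assessed, cut_after = 3L) {
  n <- nrow(assessed)
  st <- cbind(assessed$cardiac, assessed$renal, assessed$liver)
  n_eval <- rowSums(st != "NOT_EVALUABLE")
  n_resp <- rowSums(st == "RESPONSE")
  combined <- ifelse(n_eval == 0L, "NOT_EVALUABLE",
              ifelse(n_resp == n_eval, "AOR",
              ifelse(n_resp == 0L, "NOR", "MOR")))
  hr_pts <- ifelse(assessed$low_dflc,
                   ifelse(assessed$hematologic_category == "CR", 0L, 1L),
                   c(CR = 0L, VGPR = 1L, PR = 2L, NR = 3L)[
                     assessed$hematologic_category])
  or_pts <- c(AOR = 0L, MOR = 1L, NOR = 2L, NOT_EVALUABLE = NA_integer_)[
    combined]
  reason <- rep(NA_character_, n)
  reason[combined == "NOT_EVALUABLE"] <- "no evaluable organ"
  reason[is.na(assessed$hematologic_category)] <-
    "hematologic response not evaluable"
  total <- ifelse(is.na(reason), hr_pts + or_pts, NA_integer_)
  assessed$combined_or <- combined
  assessed$n_evaluable_organs <- n_eval
  assessed$n_responding_organs <- n_resp
  assessed$hr_points <- ifelse(is.na(reason), hr_pts, NA_integer_)
  assessed$or_points <- ifelse(is.na(reason), or_pts, NA_integer_)
  assessed$chor_total <- total
  assessed$chor_group <- ifelse(is.na(total), NA_character_,
                                ifelse(total <= cut_after, "GROUP1", "GROUP2"))
  assessed$exclusion_reason <- reason
  assessed
}

#' Re-derive the CHOR two-group partition from survival data
#'
#' Reproduces the grouping construction: overall-survival hazard ratios
#' for scores 1-5 relative to score 0 are estimated from a Cox model with
#' the score as a six-level factor, and the score scale is then split into
#' two contiguous blocks.  Because "group scores with similar hazard
#' ratios" is not by itself an algorithm, the split is chosen by
#' evaluating every contiguous cut of \{0..5\} and keeping the one that
#' maximises the two-group log-rank statistic; the per-score hazard ratios
#' are returned alongside so the chosen cut can be audited against them.
#'
#' @param scores Integer vector of per-patient CHOR totals (0-5).
#' @param times Follow-up in months.
#' @param events Logical/0-1 death indicators.
#' @param alpha Significance level used to flag a non-separating cut.
#' @return A list of class `"chor_grouping"`: `per_score_hr` (named hazard
#'   ratios vs score 0, NA where inestimable), `hr_ci` (matrix of 95%
#'   bounds), `undefined_scores` (scores present but with no events),
#'   `cut_after` (last score in the lower block), `cut_table` (log-rank
#'   chi-square per candidate cut), `logrank_p` for the chosen cut,
#'   `p_adjusted` (Bonferroni over candidate cuts, since the cut is
#'   selected as the maximum statistic) and `separating` (logical, based
#'   on the adjusted p).
#' @examples
#' set.seed(1)
#' sc <- sample(0:5, 300, replace = TRUE)
#' tm <- rexp(300, 0.01 * ifelse(sc >= 4, 3, 1))
#' gr <- build_grouping(sc, pmin(tm, 100), tm <= 100)
#' gr$cut_after
#' @export
build_grouping <- function(scores, times, events, alpha = 0.05) {
  stopifnot(length(scores) == length(times),
            length(times) == length(events))
  if (any(is.na(scores) | is.na(times) | is.na(events)))
    stop("scores, times and events must be complete", call. = FALSE)
  if (!all(scores %in% 0:5)) stop("scores must lie in 0..5", call. = FALSE)
  events <- as.integer(events)
  present <- sort(unique(scores))
  if (length(present) < 2L)
    stop("need at least two distinct scores to construct groups",
         call. = FALSE)
  ev_per <- vapply(present, function(s) sum(events[scores == s]), integer(1))
  undefined <- present[ev_per == 0L]

  fac <- factor(scores, levels = present)
  fit <- survival::coxph(survival::Surv(times, events) ~ fac, ties = "efron")
  co <- summary(fit)$conf.int
  per_score_hr <- setNames(rep(NA_real_, 5), as.character(1:5))
  hr_ci <- matrix(NA_real_, 5, 2,
                  dimnames = list(as.character(1:5), c("lower", "upper")))
  est_scores <- present[-1L]  # reference = lowest present score
  per_score_hr[as.character(est_scores)] <- co[, "exp(coef)"]
  hr_ci[as.character(est_scores), ] <- co[, c("lower .95", "upper .95")]
  per_score_hr[as.character(intersect(undefined, 1:5))] <- NA_real_

  # candidate cuts: after each score that leaves data on both sides
  cuts <- 0:4
  ok <- vapply(cuts, function(k) any(scores <= k) && any(scores > k),
               logical(1))
  cuts <- cuts[ok]
  chisq <- vapply(cuts, function(k) {
    g <- scores > k
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }, numeric(1))
  best <- which.max(chisq)
  cut_after <- cuts[best]
  p <- pchisq(chisq[best], df = 1, lower.tail = FALSE)
  # the cut was selected as the maximum over candidate cuts, so the
  # separation flag uses a Bonferroni-corrected p-value
  p_adj <- min(1, p * length(cuts))
  structure(list(
    per_score_hr = per_score_hr, hr_ci = hr_ci,
    undefined_scores = undefined,
    cut_after = cut_after,
    cut_table = data.frame(cut_after = cuts, logrank_chisq = chisq),
    logrank_p = p, p_adjusted = p_adj, separating = p_adj < alpha
  ), class = "chor_grouping")
}

#' @export
print.chor_grouping <- function(x, ...) {
  cat("CHOR grouping construction\n")
  cat("  per-score hazard ratios vs score 0:\n")
  for (s in names(x$per_score_hr))
    cat(sprintf("    score %s: %s\n", s,
                if (is.na(x$per_score_hr[[s]])) "inestimable"
                else sprintf("%.2f (%.2f-%.2f)", x$per_score_hr[[s]],
                             x$hr_ci[s, 1], x$hr_ci[s, 2])))
  cat(sprintf("  selected cut: scores 0-%d vs %d-5 (log-rank p = %.3g)%s\n",
              x$cut_after, x$cut_after + 1, x$logrank_p,
              if (x$separating) "" else "  [non-separating]"))
  invisible(x)
}

#' Mayo 2012 cardiac-renal stage
#'
#' Stage is 1 plus the number of risk markers present: NT-proBNP at or
#' above 1800 pg/mL, troponin-T at or above 0.025 ng/mL and dFLC at or
#' above 18 mg/dL.  Used only for subgroup description; the CHOR score
#' does not depend on it.
#'
#' @param ntprobnp pg/mL.
#' @param troponin_t ng/mL.
#' @param dflc mg/dL.
#' @param cuts Named numeric thresholds (`ntprobnp`, `troponin_t`, `dflc`).
#' @return Integer stage 1-4 (vectorised).
#' @examples
#' mayo2012_stage(1625, 0.02, 19)  # 2
#' @export
mayo2012_stage <- function(ntprobnp, troponin_t, dflc,
                           cuts = c(ntprobnp = 1800, troponin_t = 0.025,
                                    dflc = 18)) {
  if (any(is.na(ntprobnp) | is.na(troponin_t) | is.na(dflc)))
    stop("all three markers are required for Mayo 2012 staging",
         call. = FALSE)
  1L + (ntprobnp >= cuts[["ntprobnp"]]) + (troponin_t >= cuts[["troponin_t"]]) +
    (dflc >= cuts[["dflc"]])
}
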