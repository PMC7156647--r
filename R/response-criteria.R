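#' @importFrom stats coef convolve median pchisq pnorm qnorm quantile rbinom rexp rnorm runif setNames
NULL

# Organ status and hematologic category value sets, used throughout.
.organ_levels <- c("RESPONSE", "NO_RESPONSE", "NOT_EVALUABLE")
.hr_levels <- c("CR", "VGPR", "PR", "NR")

.check_nonneg <- function(x, what) {
  if (any(!is.na(x) & x < 0))
    stop("negative ", what, " values are not permitted", call. = FALSE)
  x
}

# Vectorised hematologic classifier.  Patients with baseline dFLC below the
# low-dFLC cutoff are assessable for CR only; anyone else walks CR -> VGPR
# -> PR -> NR.  Missing immunofixation / FLC-ratio flags are treated as
# "CR not documented".  Returns NA category where the standard pathway
# cannot be resolved (landmark dFLC missing and CR not met).
.hr_classify <- function(baseline_dflc, landmark_dflc,
                         landmark_ifix_negative, landmark_flc_ratio_normal,
                         thresholds = response_thresholds()) {
  if (any(is.na(baseline_dflc)))
    stop("baseline_dflc is required for hematologic classification",
         call. = FALSE)
  .check_nonneg(baseline_dflc, "dFLC")
  .check_nonneg(landmark_dflc, "dFLC")
  n <- length(baseline_dflc)
  low <- baseline_dflc < thresholds$low_dflc_cutoff
  cr <- !is.na(landmark_ifix_negative) & landmark_ifix_negative &
    !is.na(landmark_flc_ratio_normal) & landmark_flc_ratio_normal
  cat <- rep(NA_character_, n)
  cat[cr] <- "CR"
  cat[low & !cr] <- "NR"
  std <- !low & !cr
  vgpr <- std & !is.na(landmark_dflc) & landmark_dflc < thresholds$vgpr_dflc
  cat[vgpr] <- "VGPR"
  pr <- std & !vgpr & !is.na(landmark_dflc) &
    landmark_dflc <= (1 - thresholds$pr_reduction) * baseline_dflc
  cat[pr] <- "PR"
  nr <- std & !vgpr & !pr & !is.na(landmark_dflc)
  cat[nr] <- "NR"
  list(category = cat, low_dflc_pathway = low)
}

.cardiac_classify <- function(involved, baseline, landmark,
                              thresholds = response_thresholds()) {
  .check_nonneg(baseline, "NT-proBNP")
  .check_nonneg(landmark, "NT-proBNP")
  status <- rep("NOT_EVALUABLE", length(involved))
  eval <- !is.na(involved) & involved & !is.na(baseline) & !is.na(landmark) &
    baseline >= thresholds$cardiac_eval_floor
  drop <- baseline - landmark
  resp <- eval & drop > thresholds$cardiac_abs_decrease &
    drop > thresholds$cardiac_rel_decrease * baseline
  status[eval] <- "NO_RESPONSE"
  status[resp] <- "RESPONSE"
  status
}

.renal_classify <- function(involved, on_dialysis, base_prot, land_prot,
                            base_egfr, land_egfr,
                            thresholds = response_thresholds()) {
  .check_nonneg(base_prot, "proteinuria")
  .check_nonneg(land_prot, "proteinuria")
  .check_nonneg(base_egfr, "eGFR")
  .check_nonneg(land_egfr, "eGFR")
  status <- rep("NOT_EVALUABLE", length(involved))
  eval <- !is.na(involved) & involved &
    !(!is.na(on_dialysis) & on_dialysis) &
    !is.na(base_prot) & !is.na(land_prot) &
    !is.na(base_egfr) & !is.na(land_egfr)
  prot_ok <- land_prot <= (1 - thresholds$renal_prot_reduction) * base_prot |
    land_prot < thresholds$renal_prot_floor
  egfr_ok <- land_egfr > (1 - thresholds$renal_egfr_decline) * base_egfr
  status[eval] <- "NO_RESPONSE"
  status[eval & prot_ok & egfr_ok] <- "RESPONSE"
  status
}

.liver_classify <- function(involved, baseline, landmark,
                            thresholds = response_thresholds()) {
  .check_nonneg(baseline, "alkaline phosphatase")
  .check_nonneg(landmark, "alkaline phosphatase")
  status <- rep("NOT_EVALUABLE", length(involved))
  eval <- !is.na(involved) & involved & !is.na(baseline) & !is.na(landmark)
  status[eval] <- "NO_RESPONSE"
  status[eval & landmark <= (1 - thresholds$liver_alp_reduction) * baseline] <-
    "RESPONSE"
  status
}

.get <- function(rec, field) if (is.null(rec[[field]])) NA else rec[[field]]

#' Classify hematologic response at the landmark
#'
#' Applies the consensus hematologic response criteria: complete response
#' (CR) requires negative serum and urine immunofixation together with a
#' normal free light-chain ratio; very good partial response (VGPR) is a
#' landmark dFLC below 4 mg/dL; partial response (PR) is at least a 50%
#' dFLC reduction; anything less (including progression) is no response
#' (NR).  Patients whose baseline dFLC is below 5 mg/dL carry too little
#' measurable disease for the graded criteria and are assessed for CR
#' only: non-CR is recorded as NR with `low_dflc_pathway = TRUE` (such
#' patients are scored separately, see [hematologic_points()]).
#'
#' @param rec A patient record: a list or one-row data frame with fields
#'   `baseline_dflc`, `landmark_dflc` (mg/dL), `landmark_ifix_negative`,
#'   `landmark_flc_ratio_normal`.
#' @param thresholds A [response_thresholds()] object.
#' @return A list of class `"hr_category"` with elements `category`
#'   (one of `"CR"`, `"VGPR"`, `"PR"`, `"NR"`) and `low_dflc_pathway`.
#' @examples
#' classify_hematologic(list(baseline_dflc = 19, landmark_dflc = 3.5,
#'                           landmark_ifix_negative = FALSE,
#'                           landmark_flc_ratio_normal = FALSE))
#' @export
classify_hematologic <- function(rec, thresholds = response_thresholds()) {
  out <- .hr_classify(.get(rec, "baseline_dflc"), .get(rec, "landmark_dflc"),
                      .get(rec, "landmark_ifix_negative"),
                      .get(rec, "landmark_flc_ratio_normal"), thresholds)
  if (is.na(out$category))
    stop("hematologic response not classifiable: landmark dFLC missing ",
         "and CR criteria not met", call. = FALSE)
  structure(list(category = out$category,
                 low_dflc_pathway = out$low_dflc_pathway),
            class = "hr_category")
}

#' Classify cardiac response from NT-proBNP
#'
#' A cardiac response requires an NT-proBNP decrease strictly greater than
#' 30% *and* strictly greater than 300 pg/mL from baseline.  The heart is
#' evaluable only when involved, both measurements are present, and
#' baseline NT-proBNP is at least 650 pg/mL.
#'
#' @param rec A patient record with `heart_involved`, `baseline_ntprobnp`
#'   and `landmark_ntprobnp` (pg/mL).
#' @inheritParams classify_hematologic
#' @return `"RESPONSE"`, `"NO_RESPONSE"` or `"NOT_EVALUABLE"`.
#' @examples
#' classify_cardiac(list(heart_involved = TRUE,
#'                       baseline_ntprobnp = 2000, landmark_ntprobnp = 1300))
#' @export
classify_cardiac <- function(rec, thresholds = response_thresholds()) {
  .cardiac_classify(.get(rec, "heart_involved"),
                    .get(rec, "baseline_ntprobnp"),
                    .get(rec, "landmark_ntprobnp"), thresholds)
}

#' Classify renal response from proteinuria and eGFR
#'
#' A renal response is a proteinuria reduction of at least 30% from
#' baseline (or a landmark value under 500 mg/24 h) without an eGFR
#' decline of 25% or more.  Patients on dialysis at baseline are excluded
#' from renal response assessment and return `"NOT_EVALUABLE"`.
#'
#' @param rec A patient record with `kidney_involved`,
#'   `on_dialysis_at_baseline`, `baseline_proteinuria`,
#'   `landmark_proteinuria` (mg/24 h), `baseline_egfr`, `landmark_egfr`.
#' @inheritParams classify_hematologic
#' @return `"RESPONSE"`, `"NO_RESPONSE"` or `"NOT_EVALUABLE"`.
#' @export
classify_renal <- function(rec, thresholds = response_thresholds()) {
  .renal_classify(.get(rec, "kidney_involved"),
                  .get(rec, "on_dialysis_at_baseline"),
                  .get(rec, "baseline_proteinuria"),
                  .get(rec, "landmark_proteinuria"),
                  .get(rec, "baseline_egfr"),
                  .get(rec, "landmark_egfr"), thresholds)
}

#' Classify hepatic response from alkaline phosphatase
#'
#' A liver response is an alkaline-phosphatase reduction of at least 50%
#' from baseline (boundary inclusive).
#'
#' @param rec A patient record with `liver_involved`, `baseline_alp` and
#'   `landmark_alp` (U/L).
#' @inheritParams classify_hematologic
#' @return `"RESPONSE"`, `"NO_RESPONSE"` or `"NOT_EVALUABLE"`.
#' @export
classify_liver <- function(rec, thresholds = response_thresholds()) {
  .liver_classify(.get(rec, "liver_involved"),
                  .get(rec, "baseline_alp"),
                  .get(rec, "landmark_alp"), thresholds)
}

#' Assess one patient's hematologic and organ responses
#'
#' Bundles [classify_hematologic()] and the three organ classifiers into a
#' single landmark response assessment.  Uninvolved organs are
#' `"NOT_EVALUABLE"` by construction.
#'
#' @inheritParams classify_hematologic
#' @return An object of class `"chor_assessment"`: a list with
#'   `patient_id`, `hematologic` (an `"hr_category"`), `cardiac`, `renal`,
#'   `liver` statuses and `landmark_months`.
#' @examples
#' rec <- list(patient_id = "pt1", baseline_dflc = 19,
#'             landmark_ifix_negative = TRUE, landmark_flc_ratio_normal = TRUE,
#'             landmark_dflc = 1, heart_involved = TRUE,
#'             baseline_ntprobnp = 2000, landmark_ntprobnp = 1300,
#'             kidney_involved = FALSE, liver_involved = FALSE,
#'             landmark_months = 6)
#' assess_patient(rec)
#' @export
assess_patient <- function(rec, thresholds = response_thresholds()) {
  hr <- tryCatch(classify_hematologic(rec, thresholds), error = function(e)
    stop("patient ", .get(rec, "patient_id"), ": ", conditionMessage(e),
         call. = FALSE))
  structure(list(
    patient_id = .get(rec, "patient_id"),
    hematologic = hr,
    cardiac = classify_cardiac(rec, thresholds),
    renal = classify_renal(rec, thresholds),
    liver = classify_liver(rec, thresholds),
    landmark_months = .get(rec, "landmark_months")
  ), class = "chor_assessment")
}

#' @export
print.chor_assessment <- function(x, ...) {
  cat(sprintf("Landmark response assessment (%s months)%s\n",
              format(x$landmark_months),
              if (is.na(x$patient_id)) "" else paste0(" - ", x$patient_id)))
  cat(sprintf("  hematologic: %s%s\n", x$hematologic$category,
              if (x$hematologic$low_dflc_pathway) " (low-dFLC pathway)" else ""))
  cat(sprintf("  cardiac: %s\n  renal:   %s\n  liver:   %s\n",
              x$cardiac, x$renal, x$liver))
  invisible(x)
}

#' Assess a whole cohort
#'
#' Vectorised equivalent of [assess_patient()].  Rows whose hematologic
#' response cannot be resolved (missing landmark data) get an NA category
#' rather than an error, so that the pipeline can report them as excluded
#' with a reason.
#'
#' @param cohort A data frame with the patient-record columns (see
#'   [read_cohort()] for the data dictionary).
#' @inheritParams classify_hematologic
#' @return `cohort` with columns `hematologic_category`, `low_dflc`,
#'   `cardiac`, `renal`, `liver` appended.
#' @export
assess_cohort <- function(cohort, thresholds = response_thresholds()) {
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else
    rep(NA, nrow(cohort))
  hr <- .hr_classify(col("baseline_dflc"), col("landmark_dflc"),
                     col("landmark_ifix_negative"),
                     col("landmark_flc_ratio_normal"), thresholds)
  cohort$hematologic_category <- hr$category
  cohort$low_dflc <- hr$low_dflc_pathway
  cohort$cardiac <- .cardiac_classify(col("heart_involved"),
                                      col("baseline_ntprobnp"),
                                      col("landmark_ntprobnp"), thresholds)
  cohort$renal <- .renal_classify(col("kidney_involved"),
                                  col("on_dialysis_at_baseline"),
                                  col("baseline_proteinuria"),
                                  col("landmark_proteinuria"),
                                  col("baseline_egfr"), col("landmark_egfr"),
                                  thresholds)
  cohort$liver <- .liver_classify(col("liver_involved"), col("baseline_alp"),
                                  col("landmark_alp"), thresholds)
  cohort
}
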