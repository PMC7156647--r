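#' Response-criteria thresholds
#'
#' All numeric cut-offs used by the hematologic and organ response
#' classifiers live in this one object so they can be audited or, where a
#' site uses variant criteria, overridden.  Defaults follow the consensus
#' criteria used in AL amyloidosis practice:
#'
#' * hematologic: CR requires negative serum *and* urine immunofixation
#'   plus a normal free light-chain ratio; VGPR is a landmark dFLC below
#'   4 mg/dL; PR is a dFLC reduction of at least 50%.  Patients with a
#'   baseline dFLC below 5 mg/dL are assessable for CR only.
#' * cardiac: NT-proBNP decrease strictly greater than 30% *and* than
#'   300 pg/mL, evaluable only when baseline NT-proBNP is at least
#'   650 pg/mL.
#' * renal: proteinuria reduction of at least 30% (or landmark
#'   proteinuria under 500 mg/24 h) without an eGFR decline of 25% or
#'   more.
#' * liver: alkaline phosphatase reduction of at least 50%.
#'
#' Relative thresholds phrased "at least" are inclusive; the cardiac
#' "greater than" thresholds are strict, matching the wording of the
#' criteria they come from.
#'
#' @param low_dflc_cutoff mg/dL below which baseline dFLC puts a patient on
#'   the CR-only assessment pathway.
#' @param vgpr_dflc mg/dL; landmark dFLC below this is VGPR.
#' @param pr_reduction minimum fractional dFLC reduction for PR (inclusive).
#' @param cardiac_rel_decrease fractional NT-proBNP decrease required
#'   (strict).
#' @param cardiac_abs_decrease pg/mL NT-proBNP decrease required (strict).
#' @param cardiac_eval_floor pg/mL; baseline NT-proBNP below this makes the
#'   heart non-evaluable.
#' @param renal_prot_reduction minimum fractional proteinuria reduction
#'   (inclusive).
#' @param renal_prot_floor mg/24 h; landmark proteinuria strictly below this
#'   also qualifies.
#' @param renal_egfr_decline fractional eGFR decline that voids a renal
#'   response (inclusive).
#' @param liver_alp_reduction minimum fractional alkaline-phosphatase
#'   reduction (inclusive).
#'
#' @return A list of class `"chor_thresholds"`.
#' @examples
#' response_thresholds()
#' @export
response_thresholds <- function(low_dflc_cutoff = 5,
                                vgpr_dflc = 4,
                                pr_reduction = 0.5,
                                cardiac_rel_decrease = 0.30,
                                cardiac_abs_decrease = 300,
                                cardiac_eval_floor = 650,
                                renal_prot_reduction = 0.30,
                                renal_prot_floor = 500,
                                renal_egfr_decline = 0.25,
                                liver_alp_reduction = 0.5) {
  th <- list(
    low_dflc_cutoff = low_dflc_cutoff,
    vgpr_dflc = vgpr_dflc,
    pr_reduction = pr_reduction,
    cardiac_rel_decrease = cardiac_rel_decrease,
    cardiac_abs_decrease = cardiac_abs_decrease,
    cardiac_eval_floor = cardiac_eval_floor,
    renal_prot_reduction = renal_prot_reduction,
    renal_prot_floor = renal_prot_floor,
    renal_egfr_decline = renal_egfr_decline,
    liver_alp_reduction = liver_alp_reduction
  )
  bad <- names(th)[!vapply(th, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0, logical(1))]
  if (length(bad))
    stop("thresholds must be single non-negative numbers: ",
         paste(bad, collapse = ", "))
  structure(th, class = "chor_thresholds")
}

#' @export
print.chor_thresholds <- function(x, ...) {
  cat("CHOR response-criteria thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}
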