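#' Round-half-away-from-zero percentage
#'
#' Renders a numerator/denominator as an integer percent using
#' round-half-away-from-zero (the convention of clinical results tables,
#' where 45/119 prints as 38%), not banker's rounding.
#'
#' @param num,den Numerator and denominator counts.
#' @return Integer percent (vectorised).
#' @examples
#' render_pct(45, 119)  # 38
#' @export
render_pct <- function(num, den) {
  x <- 100 * num / den
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# FNV-1a hash of a serialised object, for run provenance.
.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    h <- (h * 0x01000193) %% 4294967296         # exact below 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.required_columns <- c(
  "patient_id", "baseline_dflc", "landmark_dflc", "landmark_ifix_negative",
  "landmark_flc_ratio_normal", "baseline_ntprobnp", "landmark_ntprobnp",
  "baseline_proteinuria", "landmark_proteinuria", "baseline_egfr",
  "landmark_egfr", "baseline_alp", "landmark_alp", "heart_involved",
  "kidney_involved", "liver_involved", "on_dialysis_at_baseline",
  "os_time", "os_event", "landmark_months")

.optional_columns <- c(
  "age", "sex_male", "baseline_ifix_negative", "baseline_flc_ratio_normal",
  "baseline_troponin_t", "dialysis_time", "dialysis_event",
  "latent_hr_category", "latent_cardiac", "latent_renal", "latent_liver")

#' Read and validate a cohort CSV
#'
#' One row per patient; column names follow the package data dictionary
#' (see `system.file("extdata", "cohort-dictionary.csv", package =
#' "alchor")`).  Missing values are empty cells.  dFLC units must be
#' declared in a YAML sidecar (`dflc_units: mg/dL` or `mg/L`); mg/L
#' values are converted to the internal mg/dL convention (1 mg/dL =
#' 10 mg/L).  Silent unit guessing is deliberately not supported.
#'
#' Rows whose `landmark_months` falls outside the accepted assessment
#' window (nominal landmark +/- 2 months) are flagged ineligible rather
#' than interpolated.
#'
#' @param path CSV file path.
#' @param units_sidecar YAML sidecar path; defaults to
#'   `<path>.units.yaml`.
#' @param nominal_landmark Nominal landmark in months (6 or 12).
#' @param window Half-width of the accepted assessment window (months).
#' @return A validated data frame with a `landmark_eligible` column; the
#'   per-row validation report (missing fields) is attached as attribute
#'   `"validation"`.
#' @export
read_cohort <- function(path, units_sidecar = paste0(path, ".units.yaml"),
                        nominal_landmark = 6, window = 2) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (!file.exists(units_sidecar))
    stop("units sidecar not found (", units_sidecar, "): dFLC units must ",
         "be declared explicitly", call. = FALSE)
  units <- yaml::read_yaml(units_sidecar)
  if (is.null(units$dflc_units) || !units$dflc_units %in% c("mg/dL", "mg/L"))
    stop("units sidecar must declare dflc_units as mg/dL or mg/L",
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)

  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols))
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), c(.required_columns, .optional_columns))
  if (length(unknown))
    stop("unknown columns in cohort file: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  for (nm in grep("involved|negative|normal|dialysis_at|event|sex_male",
                  names(df), value = TRUE))
    df[[nm]] <- as.logical(df[[nm]])

  if (units$dflc_units == "mg/L") {
    df$baseline_dflc <- df$baseline_dflc / 10
    df$landmark_dflc <- df$landmark_dflc / 10
  }

  biomarkers <- grep("dflc|ntprobnp|proteinuria|egfr|alp|troponin|time",
                     names(df), value = TRUE)
  bad <- list()
  for (nm in biomarkers) {
    neg <- which(!is.na(df[[nm]]) & df[[nm]] < 0)
    if (length(neg)) bad[[nm]] <- neg
  }
  if (length(bad))
    stop("negative values are not permitted: ",
         paste(vapply(names(bad), function(nm)
           sprintf("%s (rows %s)", nm,
                   paste(bad[[nm]], collapse = ",")), character(1)),
           collapse = "; "), call. = FALSE)

  df$landmark_eligible <- !is.na(df$landmark_months) &
    abs(df$landmark_months - nominal_landmark) <= window

  report <- do.call(rbind, lapply(.required_columns, function(nm) {
    rows <- which(is.na(df[[nm]]))
    if (!length(rows)) return(NULL)
    data.frame(row = rows, field = nm, issue = "missing",
               stringsAsFactors = FALSE)
  }))
  attr(df, "validation") <- if (is.null(report))
    data.frame(row = integer(), field = character(), issue = character())
  else report
  df
}

#' Write a cohort CSV with its units sidecar
#'
#' Writes the same CSV dialect [read_cohort()] consumes, plus a YAML
#' sidecar declaring `dflc_units: mg/dL` and recording the generator seed
#' when the cohort carries one.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c(.required_columns, .optional_columns), names(cohort))
  utils::write.csv(cohort[, keep], path, row.names = FALSE, na = "")
  meta <- list(dflc_units = "mg/dL")
  if (!is.null(attr(cohort, "seed"))) meta$seed <- attr(cohort, "seed")
  yaml::write_yaml(meta, paste0(path, ".units.yaml"))
  invisible(path)
}

.km_block <- function(times, events) {
  km <- km_estimate(times, events)
  list(n = km$n, events = km$n_events,
       median = if (km$median_reached) km$median else NULL,
       median_reached = km$median_reached,
       median_ci = as.list(ifelse(is.na(km$median_ci), NA, km$median_ci)))
}

# survival contrast of a categorical response variable, reference level
# first; Cox HR for each non-reference level vs reference
.contrast_block <- function(times, events, cat, levels) {
  present <- levels[levels %in% cat]
  out <- list(n_per_group = as.list(table(factor(cat, levels = levels))))
  out$km <- lapply(setNames(present, present), function(lv)
    .km_block(times[cat == lv], events[cat == lv]))
  if (length(present) < 2L) {
    out$non_separating <- TRUE
    return(out)
  }
  out$logrank_p <- logrank_test(times, events, cat)$p
  ref <- present[1]
  out$hazard_ratios <- lapply(setNames(present[-1], present[-1]), function(lv) {
    sel <- cat %in% c(ref, lv)
    cb <- cox_binary(times[sel], events[sel], cat[sel] == lv)
    list(vs = ref, hr = cb$hr, ci = cb$ci, p = cb$p, monotone = cb$monotone)
  })
  out
}

#' Run the full landmark analysis on a cohort
#'
#' Applies response classification, composite CHOR scoring and the
#' validating survival analyses: overall survival by combined organ
#' response (all patients, the more-than-one-organ subset, the
#' heart-involved subset), by CHOR group, concordance comparisons of the
#' CHOR grouping against CR-vs-not and AOR-vs-not risk indicators, and
#' dialysis-free survival by renal response when renal follow-up columns
#' are present.
#'
#' @param records Cohort data frame (from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param thresholds [response_thresholds()] used for classification.
#' @param landmark_months Nominal landmark, recorded in the report.
#' @param seed Seed recorded in provenance (the analysis itself is
#'   deterministic).
#' @return A list of class `"chor_report"`.
#' @export
run_analysis <- function(records, thresholds = response_thresholds(),
                         landmark_months = 6, seed = NULL) {
  scored <- score_cohort(assess_cohort(records, thresholds))
  ok <- is.na(scored$exclusion_reason)
  if (!any(ok))
    stop("no scoreable patients; exclusion reasons: ",
         paste(sprintf("%s (n=%d)", names(table(scored$exclusion_reason)),
                       table(scored$exclusion_reason)), collapse = ", "),
         call. = FALSE)
  sc <- scored[ok, ]
  n_input <- nrow(scored)

  # response rates with explicit numerators/denominators
  std <- !sc$low_dflc
  hr_rates <- lapply(setNames(.hr_levels, .hr_levels), function(cv) {
    num <- sum(sc$hematologic_category[std] == cv)
    list(num = num, den = sum(std), pct = render_pct(num, sum(std)))
  })
  low_cr <- list(num = sum(sc$low_dflc & sc$hematologic_category == "CR"),
                 den = sum(sc$low_dflc),
                 pct = if (sum(sc$low_dflc) > 0)
                   render_pct(sum(sc$low_dflc & sc$hematologic_category ==
                                    "CR"), sum(sc$low_dflc)) else NA)
  or_lv <- c("AOR", "MOR", "NOR")
  or_rates <- lapply(setNames(or_lv, or_lv), function(cv) {
    num <- sum(sc$combined_or == cv)
    list(num = num, den = nrow(sc), pct = render_pct(num, nrow(sc)))
  })
  # combined OR by hematologic depth (low-dFLC CR folded into CR,
  # low-dFLC non-CR into VGPR, matching how depth drives prognosis)
  depth <- ifelse(sc$low_dflc & sc$hematologic_category != "CR", "VGPR",
                  sc$hematologic_category)
  or_by_depth <- lapply(setNames(.hr_levels, .hr_levels), function(dv) {
    sel <- depth == dv
    lapply(setNames(or_lv, or_lv), function(cv)
      list(num = sum(sc$combined_or[sel] == cv), den = sum(sel),
           pct = if (sum(sel) > 0) render_pct(sum(sc$combined_or[sel] == cv),
                                              sum(sel)) else NA))
  })

  chor_distribution <- list(
    scores = as.list(table(factor(sc$chor_total, levels = 0:5))),
    groups = as.list(table(factor(sc$chor_group,
                                  levels = c("GROUP1", "GROUP2")))))

  have_surv <- all(c("os_time", "os_event") %in% names(sc)) &&
    !anyNA(sc$os_time) && !anyNA(sc$os_event)
  survival_blocks <- NULL
  concordance_blocks <- NULL
  if (have_surv) {
    tm <- sc$os_time; ev <- as.integer(sc$os_event)
    multi <- sc$n_evaluable_organs >= 2  # mixed responses possible
    heart <- sc$heart_involved
    g2 <- sc$chor_group == "GROUP2"
    chor_block <- .contrast_block(tm, ev, sc$chor_group,
                                  c("GROUP1", "GROUP2"))
    survival_blocks <- list(
      combined_or_overall = .contrast_block(tm, ev, sc$combined_or, or_lv),
      combined_or_multiorgan = .contrast_block(tm[multi], ev[multi],
                                               sc$combined_or[multi], or_lv),
      combined_or_heart = .contrast_block(tm[heart], ev[heart],
                                          sc$combined_or[heart], or_lv),
      chor_groups = chor_block)

    risk_chor <- as.integer(g2)
    risk_hr <- as.integer(sc$hematologic_category != "CR")
    risk_aor <- as.integer(sc$combined_or != "AOR")
    cc <- function(a, b) {
      x <- compare_c(a, b, tm, ev)
      list(c_a = x$c_a, c_b = x$c_b, delta = x$delta,
           delta_ci = as.list(x$delta_ci), p = x$p)
    }
    concordance_blocks <- list(
      chor_vs_hematologic = cc(risk_chor, risk_hr),
      chor_vs_aor = cc(risk_chor, risk_aor))

    renal_ok <- all(c("dialysis_time", "dialysis_event") %in% names(sc))
    if (renal_ok) {
      sel <- sc$kidney_involved & !sc$on_dialysis_at_baseline &
        !is.na(sc$dialysis_time) & !is.na(sc$dialysis_event)
      if (any(sel)) {
        dfs <- dialysis_free_survival(sc[sel, ],
                                      sc$renal[sel] == "RESPONSE")
        survival_blocks$dialysis_free <- list(
          n_per_group = as.list(dfs$n_per_group),
          surv_at_60m = as.list(dfs$surv_at_horizon),
          logrank_p = dfs$logrank_p, no_events = dfs$no_events)
      }
    }
  }

  excl <- table(scored$exclusion_reason[!ok])
  structure(list(
    schema_version = "1.0",
    cohort_summary = list(
      n_input = n_input, n_scored = nrow(sc), n_excluded = n_input - nrow(sc),
      exclusions = as.list(excl),
      landmark_months = landmark_months,
      heart_involved = sum(sc$heart_involved),
      kidney_involved = sum(sc$kidney_involved),
      liver_involved = sum(sc$liver_involved),
      multi_organ = sum(sc$n_evaluable_organs >= 2)),
    response_rates = list(hematologic = hr_rates, low_dflc_cr = low_cr,
                          combined_or = or_rates,
                          combined_or_by_depth = or_by_depth),
    chor_distribution = chor_distribution,
    survival_blocks = survival_blocks,
    concordance_blocks = concordance_blocks,
    provenance = list(
      config_hash = .config_hash(list(thresholds = unclass(thresholds),
                                      landmark_months = landmark_months)),
      seed = seed,
      timestamp = format(Sys.time(), tz = "UTC"),
      package_version = as.character(utils::packageVersion("alchor")))
  ), class = "chor_report")
}

#' @export
print.chor_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("CHOR landmark analysis: %d patients (%d scored, %d excluded)\n",
              cs$n_input, cs$n_scored, cs$n_excluded))
  rr <- x$response_rates
  cat("  hematologic (standard pathway): ",
      paste(sprintf("%s %d%% (%d/%d)", names(rr$hematologic),
                    vapply(rr$hematologic, `[[`, 0L, "pct"),
                    vapply(rr$hematologic, `[[`, 0L, "num"),
                    vapply(rr$hematologic, `[[`, 0L, "den")),
            collapse = ", "), "\n", sep = "")
  cat("  combined OR: ",
      paste(sprintf("%s %d%% (%d/%d)", names(rr$combined_or),
                    vapply(rr$combined_or, `[[`, 0L, "pct"),
                    vapply(rr$combined_or, `[[`, 0L, "num"),
                    vapply(rr$combined_or, `[[`, 0L, "den")),
            collapse = ", "), "\n", sep = "")
  g <- x$chor_distribution$groups
  cat(sprintf("  CHOR groups: GROUP1 %d, GROUP2 %d\n",
              g$GROUP1, g$GROUP2))
  if (!is.null(x$survival_blocks$chor_groups$hazard_ratios)) {
    hrb <- x$survival_blocks$chor_groups$hazard_ratios$GROUP2
    cat(sprintf("  OS, group 2 vs 1: HR %.2f (%.2f-%.2f), p = %.3g\n",
                hrb$hr, hrb$ci[1], hrb$ci[2], hrb$p))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (schema-versioned; "not reached" medians appear
#' as `null` plus a `median_reached` flag) and CSV tables for response
#' rates and the CHOR score distribution.
#'
#' @param report A `"chor_report"` from [run_analysis()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  rr <- report$response_rates
  tab <- do.call(rbind, lapply(names(rr$hematologic), function(nm)
    data.frame(measure = paste0("hematologic_", nm),
               num = rr$hematologic[[nm]]$num, den = rr$hematologic[[nm]]$den,
               pct = rr$hematologic[[nm]]$pct)))
  tab <- rbind(tab, do.call(rbind, lapply(names(rr$combined_or), function(nm)
    data.frame(measure = paste0("combined_or_", nm),
               num = rr$combined_or[[nm]]$num, den = rr$combined_or[[nm]]$den,
               pct = rr$combined_or[[nm]]$pct))))
  rates_path <- file.path(outdir, "response_rates.csv")
  utils::write.csv(tab, rates_path, row.names = FALSE)
  dist_path <- file.path(outdir, "chor_distribution.csv")
  utils::write.csv(
    data.frame(score = 0:5,
               n = unlist(report$chor_distribution$scores, use.names = FALSE)),
    dist_path, row.names = FALSE)
  invisible(c(json_path, rates_path, dist_path))
}
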