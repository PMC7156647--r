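test_that("hematologic classification covers CR, VGPR, PR, NR and boundaries", {
  # CR requires negative immunofixation AND normal FLC ratio
  cr <- classify_hematologic(make_record(landmark_ifix_negative = TRUE,
                                         landmark_flc_ratio_normal = TRUE))
  expect_equal(cr$category, "CR")
  expect_false(cr$low_dflc_pathway)
  expect_equal(classify_hematologic(
    make_record(landmark_ifix_negative = TRUE,
                landmark_flc_ratio_normal = FALSE,
                landmark_dflc = 3.5))$category, "VGPR")
  # VGPR: landmark dFLC below 4 mg/dL
  expect_equal(classify_hematologic(
    make_record(landmark_dflc = 3.5))$category, "VGPR")
  expect_equal(classify_hematologic(
    make_record(landmark_dflc = 4))$category, "PR")  # 4 is not < 4
  # PR: at least 50% reduction (inclusive)
  expect_equal(classify_hematologic(
    make_record(baseline_dflc = 20, landmark_dflc = 10))$category, "PR")
  expect_equal(classify_hematologic(
    make_record(baseline_dflc = 20, landmark_dflc = 10.01))$category, "NR")
})

test_that("low-dFLC patients are assessed for CR only and flagged", {
  low_cr <- classify_hematologic(make_record(baseline_dflc = 4.2,
                                             landmark_ifix_negative = TRUE,
                                             landmark_flc_ratio_normal = TRUE))
  expect_equal(low_cr$category, "CR")
  expect_true(low_cr$low_dflc_pathway)
  # deep dFLC fall without immunofixation negativity is still NR here
  low_nr <- classify_hematologic(make_record(baseline_dflc = 4.2,
                                             landmark_dflc = 0.5))
  expect_equal(low_nr$category, "NR")
  expect_true(low_nr$low_dflc_pathway)
})

test_that("hematologic classification validates its inputs", {
  expect_error(classify_hematologic(make_record(baseline_dflc = NA)),
               "baseline_dflc")
  expect_error(classify_hematologic(make_record(baseline_dflc = -1)),
               "negative")
  expect_error(classify_hematologic(make_record(landmark_dflc = NA)),
               "not classifiable")
})

test_that("cardiac response needs both relative and absolute NT-proBNP drops", {
  resp <- function(b, l) classify_cardiac(make_record(baseline_ntprobnp = b,
                                                      landmark_ntprobnp = l))
  expect_equal(resp(2000, 1300), "RESPONSE")      # 35% and 700 pg/mL
  expect_equal(resp(2000, 1500), "NO_RESPONSE")   # 25% fails relative
  expect_equal(resp(900, 620), "NO_RESPONSE")     # 31% but only 280 pg/mL
  expect_equal(resp(2000, 1400), "NO_RESPONSE")   # exactly 30%: strict
  expect_equal(resp(600, 100), "NOT_EVALUABLE")   # below 650 floor
  expect_equal(classify_cardiac(make_record(heart_involved = FALSE,
                                            baseline_ntprobnp = 2000,
                                            landmark_ntprobnp = 100)),
               "NOT_EVALUABLE")
  expect_equal(classify_cardiac(make_record(landmark_ntprobnp = NA)),
               "NOT_EVALUABLE")
})

test_that("doubling NT-proBNP preserves the relative but not absolute clause", {
  # 31% decrease, 248 pg/mL: short of 300 absolute; doubled it passes
  expect_equal(classify_cardiac(make_record(baseline_ntprobnp = 800,
                                            landmark_ntprobnp = 552)),
               "NO_RESPONSE")
  expect_equal(classify_cardiac(make_record(baseline_ntprobnp = 1600,
                                            landmark_ntprobnp = 1104)),
               "RESPONSE")
})

test_that("renal response combines proteinuria improvement with eGFR stability", {
  resp <- function(...) classify_renal(make_record(...))
  expect_equal(resp(baseline_proteinuria = 5000, landmark_proteinuria = 3000,
                    baseline_egfr = 65, landmark_egfr = 60), "RESPONSE")
  expect_equal(resp(baseline_proteinuria = 5000, landmark_proteinuria = 3000,
                    baseline_egfr = 65, landmark_egfr = 45), "NO_RESPONSE")
  # landmark below 500 mg/24h qualifies even without a 30% fall
  expect_equal(resp(baseline_proteinuria = 600, landmark_proteinuria = 450),
               "RESPONSE")
  expect_equal(resp(on_dialysis_at_baseline = TRUE), "NOT_EVALUABLE")
  expect_equal(resp(kidney_involved = FALSE), "NOT_EVALUABLE")
})

test_that("liver response is a 50% ALP reduction, boundary inclusive", {
  resp <- function(l) classify_liver(make_record(landmark_alp = l))
  expect_equal(resp(140), "RESPONSE")
  expect_equal(resp(160), "NO_RESPONSE")
  expect_equal(resp(150), "RESPONSE")  # exactly 50%
  expect_equal(classify_liver(make_record(liver_involved = FALSE)),
               "NOT_EVALUABLE")
})

test_that("assess_patient composes the classifiers and is idempotent", {
  rec <- make_record(landmark_ifix_negative = TRUE,
                     landmark_flc_ratio_normal = TRUE,
                     landmark_ntprobnp = 1300, landmark_proteinuria = 3000,
                     liver_involved = FALSE)
  a <- assess_patient(rec)
  expect_s3_class(a, "chor_assessment")
  expect_equal(a$hematologic$category, "CR")
  expect_equal(a$cardiac, "RESPONSE")
  expect_equal(a$renal, "RESPONSE")
  expect_equal(a$liver, "NOT_EVALUABLE")
  expect_identical(a, assess_patient(rec))

  dial <- assess_patient(make_record(heart_involved = FALSE,
                                     liver_involved = FALSE,
                                     on_dialysis_at_baseline = TRUE))
  expect_true(all(c(dial$cardiac, dial$renal, dial$liver) == "NOT_EVALUABLE"))

  liv <- assess_patient(make_record(heart_involved = FALSE,
                                    kidney_involved = FALSE,
                                    baseline_dflc = 20, landmark_dflc = 10,
                                    landmark_alp = 140))
  expect_equal(liv$hematologic$category, "PR")
  expect_equal(liv$liver, "RESPONSE")
  expect_equal(liv$cardiac, "NOT_EVALUABLE")
})

test_that("uninvolved organs are never evaluable across random records", {
  set.seed(42)
  for (i in 1:50) {
    rec <- make_record(
      heart_involved = runif(1) < 0.5,
      kidney_involved = runif(1) < 0.5,
      liver_involved = TRUE,  # keep >= 1 involved
      baseline_ntprobnp = runif(1, 100, 5000),
      landmark_ntprobnp = runif(1, 100, 5000),
      landmark_proteinuria = runif(1, 100, 8000),
      landmark_alp = runif(1, 50, 500))
    a <- assess_patient(rec)
    if (!rec$heart_involved) expect_equal(a$cardiac, "NOT_EVALUABLE")
    if (!rec$kidney_involved) expect_equal(a$renal, "NOT_EVALUABLE")
  }
})

test_that("assess_cohort matches per-record assessment", {
  set.seed(7)
  cohort <- simulate_cohort(mayo_default_config(n_patients = 40), seed = 7)
  assessed <- assess_cohort(cohort)
  for (i in seq_len(nrow(cohort))) {
    a <- assess_patient(as.list(cohort[i, ]))
    expect_equal(assessed$hematologic_category[i], a$hematologic$category)
    expect_equal(assessed$cardiac[i], a$cardiac)
    expect_equal(assessed$renal[i], a$renal)
    expect_equal(assessed$liver[i], a$liver)
  }
})
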