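Package: alchor
Title: Composite Hematologic and Organ Response (CHOR) Scoring for AL
    Amyloidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies hematologic and organ (heart, kidney, liver)
    responses in light-chain (AL) amyloidosis at a post-treatment landmark,
    combines them into the 0-5 composite hematologic plus organ response
    (CHOR) score and its two-group prognostic partition, and provides the
    landmark survival machinery used to validate such composite endpoints:
    Kaplan-Meier estimation, log-rank tests, Cox proportional-hazards
    ratios, Harrell's concordance with paired jackknife comparison, and
    dialysis-free survival among renally involved patients.  A seeded
    synthetic-cohort generator emulating the structure of large referral
    cohorts makes every pipeline stage testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
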