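---
title: "The composite hematologic and organ response (CHOR) model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The composite hematologic and organ response (CHOR) model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchor)
```

## The clinical problem

In light-chain (AL) amyloidosis a plasma-cell clone secretes misfolded
free light chains that deposit in organs — most often heart, kidney and
liver.  Treatment targets the clone, so early treatment benefit is
usually judged by the *hematologic* response (the fall of the involved
free light chain), while the *organ* response, the thing patients
actually feel, lags behind and is organ-specific.  The two assessments
can disagree: a deep hematologic response without organ improvement, or
organ recovery despite a shallow clonal response.  The CHOR model folds
both into one 0–5 score at a fixed post-treatment landmark (6 months by
default) so that a single early readout predicts overall survival.

## Response classification

All cut-offs live in `response_thresholds()` and can be overridden for
audit; the defaults are the consensus criteria used in practice:

* **Hematologic.**  CR = negative serum *and* urine immunofixation plus
  a normal free light-chain ratio; VGPR = landmark dFLC < 4 mg/dL;
  PR = dFLC reduction ≥ 50%; otherwise NR (progression is folded into
  NR — the score treats "no response or progression" identically).
  Patients with baseline dFLC < 5 mg/dL carry too little measurable
  clonal marker for the graded criteria and are assessed *for CR only*;
  non-CR is recorded as NR with `low_dflc_pathway = TRUE`.
* **Cardiac.**  NT-proBNP decrease strictly > 30% *and* > 300 pg/mL;
  evaluable only when the heart is involved and baseline NT-proBNP ≥
  650 pg/mL.
* **Renal.**  Proteinuria reduction ≥ 30% (or landmark proteinuria
  < 500 mg/24 h) *without* an eGFR decline ≥ 25%.  Patients on dialysis
  at baseline are excluded from renal assessment.
* **Hepatic.**  Alkaline-phosphatase reduction ≥ 50%.

Boundary conventions follow the wording of the criteria: "at least
30%/50%" thresholds are inclusive, the cardiac "greater than" thresholds
are strict.  A missing immunofixation or FLC-ratio result is treated as
"CR not documented", never as CR.  NYHA-class-based cardiac response is
not implemented.

dFLC is handled internally in mg/dL.  Because European centres often
report mg/L (50 mg/L = 5 mg/dL), `read_cohort()` refuses to guess: every
cohort file must carry a YAML sidecar declaring `dflc_units`.  Records
assessed outside the accepted landmark window (nominal ± 2 months) are
flagged ineligible rather than interpolated.

## The composite score

Organ statuses combine into **AOR** (response in *all*
involved-and-evaluable major organs), **MOR** (some) or **NOR** (none).
Points: hematologic CR/VGPR/PR/NR → 0/1/2/3 (low-dFLC pathway: CR → 0,
otherwise → 1, because survival of low-dFLC non-CR patients tracks the
VGPR stratum); organ AOR/MOR/NOR → 0/1/2.  The total (0–5) partitions
into group 1 (0–3) and group 2 (4–5).  Patients lacking an evaluable
hematologic marker or any evaluable organ cannot be scored and are
excluded with explicit consort-style reason codes.

`build_grouping()` re-derives the partition rather than assuming it:
it fits a Cox model with the score as a six-level factor (hazard ratios
for scores 1–5 against score 0) and then evaluates all five contiguous
cuts of {0..5}, keeping the one that maximises the two-group log-rank
statistic.  "Group scores with similar hazard ratios" is not by itself
an algorithm; the maximum-log-rank rule was chosen because it is
deterministic, reproducible, and returns the per-score hazard ratios
alongside so the published 3|4 cut can be audited against either
reading (inspecting HR magnitudes or formal testing).  Because the cut
is *selected* as a maximum over five candidates, the separation flag
uses a Bonferroni-corrected p-value; the unadjusted p for the chosen cut
is also reported.  The published 0–3 vs 4–5 partition remains the
scoring default — `build_grouping()` reproduces the construction, it
does not silently re-derive groups.

## Survival machinery

The landmark analyses use standard tools from the `survival` package
behind a stable surface: Kaplan–Meier curves with Brookmeyer–Crowley
log-log confidence intervals for the median (the method is not dictated
by the clinical literature this model comes from; log-log is the common
default and behaves at the boundaries), log-rank tests, and Cox models
with Efron tie handling, Wald intervals and two-sided tests at
α = 0.05.  The overall-survival clock starts at treatment start, with
the cohort restricted to patients alive at the landmark; this keeps
medians on the scale clinicians report.

Harrell's concordance is computed by explicit pair counting: a pair is
comparable when the member with shorter follow-up died (ties in time
only when exactly one member died); tied risk scores count one half.
`compare_c()` performs a *paired* comparison of two models on the same
patients with a leave-one-out jackknife of the concordance difference —
each subject's pair contributions are subtracted from the totals, giving
all n leave-one-out differences in O(n²) — with a normal-theory interval
and p-value.  The jackknife was chosen because the two concordances are
computed on identical subjects and are strongly dependent; an unpaired
comparison would be anticonservative.

Dialysis-free survival treats death before dialysis as independent
censoring.  Whether "dialysis-free at 5 years" should instead treat
death as a competing risk is genuinely ambiguous in the clinical
convention this package follows; censoring was chosen because it
estimates the biological rate of renal failure among those at risk, and
because the headline 88% vs 65% contrast is a calibration target of the
simulator under exactly this estimand.  A competing-risk
(Aalen–Johansen) treatment would lower both curves and is deliberately
not the default.

## The synthetic cohort generator

No patient-level data accompany the model, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes,
and the two frozen configurations `mayo_default_config()` and
`pavia_default_config()` encode the printed marginals of the two
referral cohorts (organ involvement 70/70/14% and 79/69/11%; low-dFLC
13% and 7%; the CR/VGPR/PR/NR mix among evaluable patients; dialysis
prevalence among the renally involved; baseline biomarker medians and
IQRs).

Design choices, in the order they matter:

* **Distributions.**  Published tables give medians and IQRs, not
  distributions.  Right-skewed biomarkers (dFLC, NT-proBNP,
  proteinuria, ALP, troponin-T) are log-normal with parameters solved
  from median and quartiles; age and eGFR are normal (clamped to 18–95
  years and ≥ 5 mL/min).  The implied proteinuria tail is heavy; that
  is what the printed IQR implies under log-normality and it is left
  uncorrected.
* **Involvement.**  Organ involvement is drawn independently per organ,
  *conditioned on at least one involved major organ* by sampling the
  seven admissible involvement patterns directly; the raw pattern
  weights are solved (fixed point) so that the *conditional* marginals
  equal the configured ones.  Correlation between organs is unreported
  and therefore not modelled; the more-than-one-organ fraction is a
  calibration check, not a constraint.
* **Responses.**  The hematologic category is drawn from the configured
  mix; each involved-and-evaluable organ then responds independently
  with a probability that depends on hematologic depth (low-dFLC non-CR
  patients use the VGPR depth).  Conditional independence is the
  simplest structure consistent with the printed depth-conditional
  all-organ-response rates; the per-organ probability for each depth is
  solved numerically (`solve_organ_response_probs()`) so that
  E[q^K | K ≥ 1] equals the target AOR rate, where K is the number of
  evaluable organs implied by involvement, the NT-proBNP evaluability
  floor and dialysis prevalence.  The depth-conditional AOR rate for
  patients with no hematologic response is not printed for the
  validation cohort; 5% was adopted as a realistic small value.
* **Partial-response attainability.**  A patient with baseline dFLC
  below 8 mg/dL cannot be PR: any ≥ 50% reduction already lands below
  the 4 mg/dL VGPR threshold.  The category draw is therefore
  stratified on that bound, with stratum weights chosen in closed form
  so the configured marginal mix still holds exactly.
* **Round-trip exactness.**  Landmark biomarkers are drawn uniformly
  inside the response region for responders (e.g. an NT-proBNP
  fractional decrease in (max(30%, 300 pg/mL), 80%]) and outside it for
  non-responders, so the classifiers reproduce the generator's latent
  statuses for every patient — the tests assert this at 100%.
* **Survival.**  Exponential baseline hazard by default (Weibull
  selectable), multiplied by the CHOR-group-2 hazard ratio (3.4 and 2.8
  in the two configurations, matching the published group contrasts),
  left-truncated at the landmark via the conditional quantile transform
  (the analysis cohort is alive at assessment), and administratively
  censored uniformly on [landmark, 120] months.  The baseline rate is
  anchored so that group 2's median matches the published 34 months in
  the test-cohort configuration; a single proportional-hazards
  exponential cannot match both groups' printed medians *and* the Cox
  hazard ratio at once, and hazard-ratio fidelity was preferred because
  the recovery tests are Cox-based.
* **Dialysis.**  Renally involved, non-dialysis patients receive an
  exponential time to dialysis whose rate is calibrated so that the
  5-year dialysis-free probability is 0.88 for renal responders and
  0.65 for non-responders, with death and administrative censoring
  ending follow-up.

What the generator does *not* emulate: between-organ response
correlation beyond hematologic depth, treatment-arm effects (the two
real cohorts differed sharply in transplant rates), non-proportional
hazards, loss to follow-up, and measurement error in the biomarkers.
Passing tests therefore show that the pipeline is internally coherent
and recovers known structure — not that the model would validate on an
arbitrary external cohort.

## Numerical and testing notes

Problem sizes in the test suite were chosen to make Monte-Carlo checks
informative: marginal-fidelity checks run at n = 10 000 (three binomial
standard errors), Cox parameter recovery at the real cohort's geometry
(n = 473 split 349/124, ~40% events, 200 replicates), grouping-recovery
at n = 1000 with a three-fold hazard jump (100 replicates), and the
dialysis calibration at n = 400.  Concordance uses O(n²) pair counting
(dense matrices; fine to a few thousand subjects, not intended for tens
of thousands).  All generators are deterministic under a fixed seed;
identical configuration and seed give byte-identical cohorts.

Degenerate inputs are values, not crashes, wherever a value is
defensible: "median not reached" is a flagged NA, a single-level
contrast is reported `non_separating`, a no-event arm flags the Cox fit
`monotone`, and a cohort with zero scoreable patients fails with
per-reason exclusion counts.

## Known limitations

The exact evaluability floors of the organ criteria vary slightly
across consensus documents; the values here (650 pg/mL NT-proBNP floor
in particular) are exposed in `response_thresholds()` precisely so a
site can match its local convention.  Troponin assays differ between
centres (troponin-T vs troponin-I); troponin enters only the Mayo 2012
staging helper, never a response rule.  The composite score is a
landmark endpoint: it says nothing about responses evolving after the
landmark, and time-updated scoring is out of scope.
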