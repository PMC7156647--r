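# A fully specified patient record; override fields per test.
make_record <- function(...) {
  rec <- list(
    patient_id = "pt1",
    baseline_dflc = 19, landmark_dflc = 10,
    landmark_ifix_negative = FALSE, landmark_flc_ratio_normal = FALSE,
    baseline_ntprobnp = 2000, landmark_ntprobnp = 1900,
    baseline_proteinuria = 5000, landmark_proteinuria = 4800,
    baseline_egfr = 65, landmark_egfr = 64,
    baseline_alp = 300, landmark_alp = 290,
    heart_involved = TRUE, kidney_involved = TRUE, liver_involved = TRUE,
    on_dialysis_at_baseline = FALSE,
    os_time = 48, os_event = FALSE,
    dialysis_time = 48, dialysis_event = FALSE,
    landmark_months = 6)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}

# Exhaustive O(n^2) concordance oracle, independent of the package's
# vectorised pair counting.
brute_force_c <- function(risk, times, events) {
  n <- length(times)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    first <- NA
    if (times[i] < times[j] && events[i]) first <- i
    else if (times[j] < times[i] && events[j]) first <- j
    else if (times[i] == times[j] && xor(events[i] == 1, events[j] == 1))
      first <- if (events[i]) i else j
    if (is.na(first)) next
    second <- if (first == i) j else i
    comp <- comp + 1
    if (risk[first] > risk[second]) conc <- conc + 1
    else if (risk[first] == risk[second]) conc <- conc + 0.5
  }
  conc / comp
}

# Exponential survival data with a binary group hazard contrast.
sim_two_group <- function(n1, n2, rate1, rate2, cens_max = 120) {
  g <- c(rep(0L, n1), rep(1L, n2))
  t <- rexp(n1 + n2, ifelse(g == 1, rate2, rate1))
  cens <- runif(n1 + n2, 0, cens_max)
  list(times = pmin(t, cens), events = as.integer(t <= cens), group = g)
}
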