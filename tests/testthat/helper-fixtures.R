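# Shared fixtures, built in code at test time.

# A small analysis cohort from the default synthetic generator.
make_cohort <- function(n = 1200, seed = 42, ...) {
  cfg <- registry_config(n = n, seed = seed, ...)
  apply_eligibility(generate_registry(cfg))$cohort
}

# One hand-built registry patient row plus surgery rows.  Defaults satisfy
# every eligibility rule; override a field to violate one.
make_record <- function(id, age = 70, diagnosis = "2010-06-01",
                        stage = "I", size = 30, enrollment = 1L,
                        death = NA,
                        surgeries = list(c("ablation", "2010-07-01"))) {
  patient <- data.frame(
    id = id, age_at_diagnosis = age, female = 0L, white = 1L,
    married = 1L, diagnosis_date = as.Date(diagnosis), stage = stage,
    tumor_size_mm = size, elixhauser_score = 20,
    hep_b = 0L, hep_c = 0L, viral_other = 0L, nonviral = 0L,
    alcohol = 0L, cirrhosis = 1L, portal_htn = 0L, enceph = 0L,
    enrollment_ok = enrollment, true_violation = "none",
    death_date = as.Date(death), stringsAsFactors = FALSE)
  surg <- do.call(rbind, lapply(surgeries, function(s)
    data.frame(id = id, procedure = s[1], date = as.Date(s[2]),
               stringsAsFactors = FALSE)))
  list(patient = patient, surgeries = surg)
}

make_registry <- function(records) {
  structure(list(
    patients = do.call(rbind, lapply(records, `[[`, "patient")),
    surgeries = do.call(rbind, lapply(records, `[[`, "surgeries")),
    config = NULL), class = "registry")
}

# Independent product-limit (Kaplan-Meier) oracle: plain loop over
# distinct event times.
km_oracle <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(times >= tt[i])
    d <- sum(times == tt[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# Independent two-group log-rank oracle: observed-minus-expected with
# hypergeometric variance at each distinct event time.
logrank_oracle <- function(times, events, group) {
  tt <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in tt) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
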