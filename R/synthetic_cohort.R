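# Synthetic registry generator
#
# Emulates the statistical structure the downstream analysis assumes: a
# registry of elderly early-stage liver-cancer patients with confounded
# choice between partial hepatectomy and ablation, Weibull survival on the
# proportional-hazards scale, administrative censoring at a study end date,
# and a configurable share of records that deliberately violate the
# eligibility rules so every exclusion path is exercised.

# Covariates entering the propensity model, in reporting order.
PS_COVARIATES <- c("age_std", "female", "white", "stage2", "size_std",
                   "elix_std", "hep_b", "hep_c", "viral_other", "nonviral",
                   "alcohol", "cirrhosis", "portal_htn", "enceph")
# Outcome model additionally adjusts for marital status.
OUTCOME_COVARIATES <- c("age_std", "female", "white", "married", "stage2",
                        "size_std", "elix_std", "hep_b", "hep_c",
                        "viral_other", "nonviral", "alcohol", "cirrhosis",
                        "portal_htn", "enceph")
LIVER_FLAGS <- c("hep_b", "hep_c", "viral_other", "nonviral", "alcohol",
                 "cirrhosis", "portal_htn", "enceph")

# Truncated-normal sampler whose *truncated* mean equals target_mean: the
# latent location is solved numerically, then draws come from the exact
# truncated distribution by inverse-CDF.  Keeps eligible-range covariates
# (age 66-100, tumor size 5-50 mm) matching the specified marginal mean.
rtnorm_matched <- function(n, target_mean, sd, lower, upper) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  mu <- uniroot(function(m) trunc_mean(m) - target_mean,
                interval = c(target_mean - 3 * sd, target_mean + 3 * sd))$root
  pl <- pnorm((lower - mu) / sd); pu <- pnorm((upper - mu) / sd)
  mu + sd * qnorm(runif(n, pl, pu))
}

default_covariate_spec <- function() {
  list(age = c(mean = 73.6, sd = 5.64),
       tumor_size = c(mean = 29.3, sd = 10.5),
       elixhauser = c(mean = 22.59, sd = 8.89),
       female = 0.376, white = 0.531, married = 0.585, stage2 = 0.291,
       hep_b = 0.168, hep_c = 0.465, viral_other = 0.073,
       nonviral = 0.196, alcohol = 0.193, cirrhosis = 0.832,
       portal_htn = 0.476, enceph = 0.112)
}

default_ps_coefficients <- function() {
  c(intercept = -0.3, age_std = 0.25, female = -0.16, white = 0.00,
    stage2 = 0.19, size_std = -0.52, elix_std = 0.06, hep_b = -0.29,
    hep_c = 0.12, viral_other = -0.06, nonviral = 0.37, alcohol = 0.61,
    cirrhosis = 0.84, portal_htn = 0.87, enceph = 0.42)
}

default_outcome_coefficients <- function() {
  c(age_std = 0.24, female = -0.09, white = -0.01, married = -0.18,
    stage2 = 0.15, size_std = 0.15, elix_std = 0.19, hep_b = -0.33,
    hep_c = -0.03, viral_other = 0.26, nonviral = -0.19, alcohol = 0.13,
    cirrhosis = 0.09, portal_htn = 0.65, enceph = 0.43)
}

INELIGIBLE_RULES <- c("age_low", "age_high", "missing_size", "missing_stage",
                      "missing_date", "late_surgery", "same_day",
                      "enrollment")

#' Configuration for the synthetic registry generator
#'
#' The defaults define the generator's study conditions: covariate marginals
#' matching the analysis cohort's descriptive table, a logistic
#' treatment-assignment mechanism with published-scale log-odds (continuous
#' covariates per standard deviation), and Weibull survival with
#' published-scale log-hazard effects and a true treatment log hazard ratio
#' of 0.30 (ablation vs. partial hepatectomy).
#'
#' @param n number of registry records to generate.
#' @param covariate_spec named list of covariate marginals: `age`,
#'   `tumor_size`, `elixhauser` as `c(mean=, sd=)`; the remaining entries
#'   are proportions for binary covariates.
#' @param ps_coefficients named log-odds vector (including `intercept`) for
#'   the Bernoulli treatment assignment `P(ablation | x)`; continuous
#'   covariates enter standardized.
#' @param outcome_coefficients named log-hazard vector for the Weibull
#'   survival mechanism (continuous covariates standardized).
#' @param true_log_hr treatment log hazard ratio, ablation vs. hepatectomy.
#' @param shape Weibull shape parameter k > 0.
#' @param baseline_log_rate log of the Weibull rate parameter (log lambda)
#'   at covariate means; with the defaults the implied median survival is
#'   about four years.
#' @param accrual_start,accrual_end diagnosis dates are uniform over this
#'   window.
#' @param study_end administrative censoring date (vital status is known
#'   only up to this date).
#' @param ineligible_fraction share of records injected with eligibility
#'   violations, split equally across the rule types (age out of range,
#'   missing size/stage/diagnosis date, surgery beyond one year, both
#'   procedures on the same day, enrollment gap).
#' @param crossover_rate share of eligible records that later receive the
#'   other procedure type (censored at that point by the analysis).
#' @param session_rate share of ablation records with a repeat ablation
#'   session (same type; must not trigger censoring).
#' @param latent_loading loading in (0, 1) of the shared latent severity
#'   factor that correlates the liver-disease flags.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `registry_config`.
#' @export
registry_config <- function(n,
                            covariate_spec = default_covariate_spec(),
                            ps_coefficients = default_ps_coefficients(),
                            outcome_coefficients = default_outcome_coefficients(),
                            true_log_hr = 0.30,
                            shape = 1.1,
                            baseline_log_rate = -2.4,
                            accrual_start = "2007-01-01",
                            accrual_end = "2017-12-31",
                            study_end = "2019-12-31",
                            ineligible_fraction = 0.10,
                            crossover_rate = 0.02,
                            session_rate = 0.15,
                            latent_loading = 0.5,
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0 ||
      n != round(n))
    stop_field("n", "must be a positive integer")
  check_pos(shape, "shape")
  for (nm in setdiff(names(covariate_spec),
                     c("age", "tumor_size", "elixhauser")))
    check_prob(covariate_spec[[nm]], paste0("covariate_spec$", nm))
  if (!is.numeric(ineligible_fraction) || ineligible_fraction < 0 ||
      ineligible_fraction >= 1)
    stop_field("ineligible_fraction", "must be in [0, 1)")
  check_prob(crossover_rate, "crossover_rate")
  check_prob(latent_loading, "latent_loading")
  structure(list(n = as.integer(n), covariate_spec = covariate_spec,
                 ps_coefficients = ps_coefficients,
                 outcome_coefficients = outcome_coefficients,
                 true_log_hr = true_log_hr, shape = shape,
                 baseline_log_rate = baseline_log_rate,
                 accrual_start = as.Date(accrual_start),
                 accrual_end = as.Date(accrual_end),
                 study_end = as.Date(study_end),
                 ineligible_fraction = ineligible_fraction,
                 crossover_rate = crossover_rate,
                 session_rate = session_rate,
                 latent_loading = latent_loading,
                 seed = as.integer(seed)),
            class = "registry_config")
}

# Standardize the generator's continuous covariates with the *specified*
# (true) means/sds, so coefficient magnitudes are per-SD as intended.
.standardize_true <- function(patients, spec) {
  cbind(age_std = (patients$age_at_diagnosis - spec$age["mean"]) / spec$age["sd"],
        size_std = (patients$tumor_size_mm - spec$tumor_size["mean"]) /
          spec$tumor_size["sd"],
        elix_std = (patients$elixhauser_score - spec$elixhauser["mean"]) /
          spec$elixhauser["sd"])
}

#' Draw Weibull proportional-hazards survival times
#'
#' Samples event times from the hazard
#' `h(t | x) = k * lambda * t^(k-1) * exp(x'beta + A * beta_A)` by inverse-CDF
#' sampling, then applies an administrative horizon: observed time is
#' `min(T, horizon)` and the event indicator is `T <= horizon`.
#'
#' @param covariates numeric matrix (or vector for one subject) whose
#'   columns align with `config$outcome_coefficients`.
#' @param arm 0/1 treatment indicator (1 = ablation).
#' @param config a [registry_config()]; supplies `shape`,
#'   `baseline_log_rate`, coefficient vector and `true_log_hr`.
#' @param horizon administrative censoring horizon in years (scalar or
#'   per-subject vector; `Inf` disables censoring).
#' @param u optional uniform draws (for reproducibility); defaults to
#'   `runif(n)` from the current RNG stream.
#' @return a list with numeric `time` (years) and integer `event`.
#' @export
simulate_survival <- function(covariates, arm, config, horizon = Inf,
                              u = NULL) {
  check_pos(config$shape, "shape")
  if (is.null(dim(covariates)))
    covariates <- matrix(covariates, nrow = length(arm),
                         ncol = length(covariates), byrow = TRUE)
  beta <- config$outcome_coefficients
  eta <- if (length(beta)) drop(covariates[, names(beta), drop = FALSE] %*% beta)
         else 0
  eta <- eta + arm * config$true_log_hr
  lambda <- exp(config$baseline_log_rate)
  if (is.null(u)) u <- runif(length(arm))
  t_event <- (-log(u) / (lambda * exp(eta)))^(1 / config$shape)
  list(time = pmin(t_event, horizon),
       event = as.integer(t_event <= horizon))
}

#' Generate a synthetic registry
#'
#' Produces `config$n` patient records with confounded treatment assignment
#' (Bernoulli through the logistic mechanism in `config$ps_coefficients`),
#' Weibull survival from time of surgery, administrative censoring at
#' `config$study_end`, and a share of deliberately ineligible records each
#' carrying a ground-truth violation label.  Liver-disease flags are
#' correlated through a single latent severity factor while keeping their
#' marginal prevalences exact (Gaussian-threshold construction).
#'
#' @param config a [registry_config()].
#' @return an object of class `registry`: a list with `patients` (one row
#'   per patient), `surgeries` (long format: `id`, `procedure`, `date`) and
#'   the `config`.  `patients$true_violation` records the injected
#'   eligibility violation (`"none"` for clean records).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  set.seed(config$seed)
  n <- config$n
  spec <- config$covariate_spec

  age <- rtnorm_matched(n, spec$age["mean"], spec$age["sd"], 66, 100)
  size <- rtnorm_matched(n, spec$tumor_size["mean"], spec$tumor_size["sd"],
                         5, 50)
  elix <- rnorm(n, spec$elixhauser["mean"], spec$elixhauser["sd"])
  female <- rbinom(n, 1, spec$female)
  white <- rbinom(n, 1, spec$white)
  married <- rbinom(n, 1, spec$married)
  stage <- ifelse(rbinom(n, 1, spec$stage2) == 1, "II", "I")

  # latent-severity construction: flag_j = 1{ rho*z + sqrt(1-rho^2)*e_j <
  # qnorm(p_j) } has exact marginal p_j and positive pairwise dependence.
  rho <- config$latent_loading
  z <- rnorm(n)
  liver <- sapply(LIVER_FLAGS, function(fl) {
    p <- spec[[fl]]
    as.integer(rho * z + sqrt(1 - rho^2) * rnorm(n) < qnorm(p))
  })

  accrual_days <- as.integer(config$accrual_end - config$accrual_start)
  diagnosis_date <- config$accrual_start +
    floor(runif(n, 0, accrual_days + 1))

  patients <- data.frame(
    id = seq_len(n), age_at_diagnosis = age, female = female, white = white,
    married = married, diagnosis_date = diagnosis_date, stage = stage,
    tumor_size_mm = size, elixhauser_score = elix, liver,
    enrollment_ok = 1L, true_violation = "none",
    stringsAsFactors = FALSE)

  # treatment assignment: P(ablation | x) via the logistic mechanism
  xs <- .standardize_true(patients, spec)
  covs <- cbind(intercept = 1, xs, female = female, white = white,
                married = married, stage2 = as.integer(stage == "II"),
                liver)
  gamma <- config$ps_coefficients
  eta <- drop(covs[, names(gamma)] %*% gamma)
  ablation <- rbinom(n, 1, plogis(eta))

  # waiting time diagnosis -> first surgery: lognormal, median ~71 days,
  # capped inside the one-year window for clean records
  wait <- pmin(round(rlnorm(n, log(71), 0.55)), 360)
  surgery_date <- diagnosis_date + wait

  # survival from time zero (surgery); vital status known through study_end
  surv <- simulate_survival(
    covs[, names(config$outcome_coefficients), drop = FALSE],
    ablation, config, horizon = Inf)
  death_date <- surgery_date + round(surv$time * DAYS_PER_YEAR)
  death_date[death_date > config$study_end] <- NA
  patients$death_date <- as.Date(death_date, origin = "1970-01-01")

  surgeries <- data.frame(
    id = patients$id,
    procedure = ifelse(ablation == 1, "ablation", "hepatectomy"),
    date = surgery_date, stringsAsFactors = FALSE)

  # repeat ablation sessions (same procedure type; analysis must NOT censor)
  repeat_idx <- which(ablation == 1 & runif(n) < config$session_rate)
  if (length(repeat_idx)) {
    d2 <- surgery_date[repeat_idx] + sample(30:300, length(repeat_idx), TRUE)
    keep <- is.na(patients$death_date[repeat_idx]) |
      d2 < patients$death_date[repeat_idx]
    ri <- repeat_idx[keep]
    if (length(ri))
      surgeries <- rbind(surgeries, data.frame(
        id = ri, procedure = "ablation", date = d2[keep]))
  }

  # crossover to the other procedure type (analysis censors at that date)
  cross_idx <- which(runif(n) < config$crossover_rate)
  if (length(cross_idx)) {
    d2 <- surgery_date[cross_idx] + sample(90:1000, length(cross_idx), TRUE)
    keep <- (is.na(patients$death_date[cross_idx]) |
               d2 < patients$death_date[cross_idx]) & d2 <= config$study_end
    ci <- cross_idx[keep]
    if (length(ci))
      surgeries <- rbind(surgeries, data.frame(
        id = ci,
        procedure = ifelse(ablation[ci] == 1, "hepatectomy", "ablation"),
        date = d2[keep]))
  }

  # inject ineligible records, cycling through the rule types equally
  n_bad <- round(n * config$ineligible_fraction)
  if (n_bad > 0) {
    bad_idx <- sample(n, n_bad)
    rules <- rep_len(INELIGIBLE_RULES, n_bad)
    for (j in seq_len(n_bad)) {
      i <- bad_idx[j]
      patients$true_violation[i] <- rules[j]
      switch(rules[j],
        age_low = { patients$age_at_diagnosis[i] <- runif(1, 40, 65.9) },
        age_high = { patients$age_at_diagnosis[i] <- runif(1, 100.1, 105) },
        missing_size = { patients$tumor_size_mm[i] <- NA_real_ },
        missing_stage = { patients$stage[i] <- NA_character_ },
        missing_date = { patients$diagnosis_date[i] <- as.Date(NA) },
        late_surgery = {
          shift <- sample(366:700, 1) - wait[i]
          sel <- surgeries$id == i
          surgeries$date[sel] <- surgeries$date[sel] + shift
          if (!is.na(patients$death_date[i])) {   # survival clock follows surgery
            d <- patients$death_date[i] + shift
            patients$death_date[i] <- if (d > config$study_end) as.Date(NA) else d
          }
        },
        same_day = {
          first <- min(surgeries$date[surgeries$id == i])
          other <- if (ablation[i] == 1) "hepatectomy" else "ablation"
          surgeries <- rbind(surgeries, data.frame(
            id = i, procedure = other, date = first))
        },
        enrollment = { patients$enrollment_ok[i] <- 0L })
    }
  }

  surgeries <- surgeries[order(surgeries$id, surgeries$date), ]
  rownames(surgeries) <- NULL
  structure(list(patients = patients, surgeries = surgeries,
                 config = config),
            class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf("Synthetic registry: %d patients, %d surgery records\n",
              nrow(x$patients), nrow(x$surgeries)))
  tab <- table(x$patients$true_violation)
  cat("Injected violations:\n")
  print(tab)
  invisible(x)
}

#' Write / read a registry as plain CSV
#'
#' The patient table and the long-format surgery table are written as two
#' CSV files (`patients.csv`, `surgeries.csv`) with ISO dates.
#'
#' @param registry a `registry` object.
#' @param dir output directory (created if needed).
#' @return `write_registry` returns the directory invisibly;
#'   `read_registry` returns a `registry` (without generator config).
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(registry$patients, file.path(dir, "patients.csv"),
            row.names = FALSE)
  write.csv(registry$surgeries, file.path(dir, "surgeries.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  patients <- read.csv(file.path(dir, "patients.csv"),
                       stringsAsFactors = FALSE)
  surgeries <- read.csv(file.path(dir, "surgeries.csv"),
                        stringsAsFactors = FALSE)
  for (col in c("diagnosis_date", "death_date"))
    patients[[col]] <- as.Date(patients[[col]])
  surgeries$date <- as.Date(surgeries$date)
  structure(list(patients = patients, surgeries = surgeries, config = NULL),
            class = "registry")
}
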