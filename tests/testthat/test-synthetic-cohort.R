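test_that("invalid generator configurations are rejected by field", {
  expect_error(registry_config(n = 0), "'n'")
  expect_error(registry_config(n = 100, shape = -1), "'shape'")
  expect_error(registry_config(n = 100, ineligible_fraction = 1),
               "'ineligible_fraction'")
  spec <- registry_config(n = 10)$covariate_spec
  spec$female <- 1.2
  expect_error(registry_config(n = 100, covariate_spec = spec), "female")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- registry_config(n = 500, seed = 7)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$surgeries, r2$surgeries)
  r3 <- generate_registry(registry_config(n = 500, seed = 8))
  expect_false(identical(r1$patients, r3$patients))
})

test_that("null treatment mechanism gives a balanced coin", {
  gamma0 <- registry_config(n = 10)$ps_coefficients * 0
  reg <- generate_registry(registry_config(
    n = 5000, seed = 3, ps_coefficients = gamma0, ineligible_fraction = 0))
  frac <- mean(reg$surgeries$procedure[!duplicated(reg$surgeries$id)] ==
                 "ablation")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("unit-rate null survival mechanism is unit exponential", {
  cfg <- registry_config(
    n = 10, shape = 1, baseline_log_rate = 0, true_log_hr = 0,
    outcome_coefficients = registry_config(n = 10)$outcome_coefficients * 0)
  set.seed(99)
  s <- simulate_survival(matrix(0, 10000, 15,
                                dimnames = list(NULL, names(cfg$outcome_coefficients))),
                         arm = rep(0, 10000), cfg, horizon = Inf)
  expect_true(all(s$event == 1))
  expect_lt(abs(mean(s$time) - 1), 3 / sqrt(10000))  # Exp(1): sd = 1
})

test_that("a zero horizon censors everything at time zero", {
  cfg <- registry_config(n = 10)
  set.seed(1)
  s <- simulate_survival(matrix(0, 50, 15,
                                dimnames = list(NULL, names(cfg$outcome_coefficients))),
                         arm = rep(1, 50), cfg, horizon = 0)
  expect_true(all(s$time == 0))
  expect_true(all(s$event == 0))
})

test_that("the treatment log HR scales event times as Weibull PH predicts", {
  # k = 1: treated times are reference times with rate scaled by exp(0.30),
  # so the ratio of means is exp(-0.30)
  cfg <- registry_config(
    n = 10, shape = 1, baseline_log_rate = 0, true_log_hr = 0.30,
    outcome_coefficients = registry_config(n = 10)$outcome_coefficients * 0)
  X <- matrix(0, 20000, 15,
              dimnames = list(NULL, names(cfg$outcome_coefficients)))
  set.seed(5)
  t0 <- simulate_survival(X, rep(0, 20000), cfg)$time
  set.seed(6)
  t1 <- simulate_survival(X, rep(1, 20000), cfg)$time
  ratio <- mean(t1) / mean(t0)
  expect_lt(abs(ratio - exp(-0.30)), 0.03)
})

test_that("nonpositive shape is rejected", {
  cfg <- registry_config(n = 10)
  cfg$shape <- -2
  expect_error(simulate_survival(matrix(0, 1, 15), 0, cfg), "shape")
})

test_that("empirical covariate marginals match the specification", {
  reg <- generate_registry(registry_config(n = 10000, seed = 12,
                                           ineligible_fraction = 0))
  p <- reg$patients
  spec <- registry_config(n = 10)$covariate_spec
  for (v in c("female", "white", "married", "hep_b", "hep_c", "cirrhosis",
              "portal_htn", "enceph")) {
    pv <- prop.test(sum(p[[v]]), nrow(p), p = spec[[v]])$p.value
    expect_gt(pv, 0.001)
  }
  expect_gt(prop.test(sum(p$stage == "II"), nrow(p),
                      p = spec$stage2)$p.value, 0.001)
  # continuous marginals: elixhauser is plain normal (KS); the truncated
  # age/size distributions are checked through their specified means
  ks <- ks.test(p$elixhauser_score, "pnorm", spec$elixhauser["mean"],
                spec$elixhauser["sd"])$p.value
  expect_gt(ks, 0.001)
  expect_lt(abs(mean(p$age_at_diagnosis) - spec$age["mean"]),
            4 * spec$age["sd"] / sqrt(nrow(p)))
  expect_lt(abs(mean(p$tumor_size_mm) - spec$tumor_size["mean"]),
            4 * spec$tumor_size["sd"] / sqrt(nrow(p)))
})

test_that("null coefficients decouple treatment and survival from covariates", {
  cfg <- registry_config(
    n = 8000, seed = 13, ineligible_fraction = 0, crossover_rate = 0,
    session_rate = 0, true_log_hr = 0,
    ps_coefficients = registry_config(n = 10)$ps_coefficients * 0,
    outcome_coefficients = registry_config(n = 10)$outcome_coefficients * 0)
  co <- apply_eligibility(generate_registry(cfg))$cohort
  for (v in c("age_std", "size_std", "cirrhosis", "portal_htn")) {
    expect_lt(abs(cor(co$ablation, co[[v]])), 4 / sqrt(nrow(co)))
    expect_lt(abs(cor(co$followup_years, co[[v]])), 4 / sqrt(nrow(co)))
  }
})

test_that("ineligible records carry their ground-truth violation label", {
  reg <- generate_registry(registry_config(n = 2000, seed = 4,
                                           ineligible_fraction = 0.2))
  em <- apply_eligibility(reg)
  bad <- reg$patients$true_violation != "none"
  expect_equal(sum(bad), 400)
  # every labelled record is excluded, every clean record included
  expect_setequal(em$log$reasons$id, reg$patients$id[bad])
  # each rule type is represented
  expect_setequal(unique(reg$patients$true_violation[bad]),
                  c("age_low", "age_high", "missing_size", "missing_stage",
                    "missing_date", "late_surgery", "same_day", "enrollment"))
})

test_that("registries round-trip through CSV", {
  reg <- generate_registry(registry_config(n = 120, seed = 2))
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  back <- read_registry(dir)
  expect_equal(back$patients$diagnosis_date, reg$patients$diagnosis_date)
  expect_equal(back$surgeries, reg$surgeries,
               ignore_attr = "row.names")
  em1 <- apply_eligibility(reg)
  em2 <- apply_eligibility(back)
  expect_equal(em1$cohort$followup_years, em2$cohort$followup_years)
})
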