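test_that("age and tumor-size boundaries follow the enrollment rules", {
  recs <- list(
    make_record(1, age = 65),                      # just under 66
    make_record(2, age = 66, stage = "I", size = 50,
                surgeries = list(c("ablation", "2010-07-01"))),
    make_record(3, size = 51))
  em <- apply_eligibility(make_registry(recs))
  expect_equal(em$cohort$id, 2)
  expect_equal(em$log$reasons$reason[em$log$reasons$id == 1], "age")
  expect_equal(em$log$reasons$reason[em$log$reasons$id == 3], "tumor_size")
})

test_that("a toy registry attrition matches its construction rule by rule", {
  recs <- list(
    make_record(1, age = 64),
    make_record(2, age = 101),
    make_record(3, diagnosis = NA),
    make_record(4, stage = NA),
    make_record(5, stage = "other"),
    make_record(6, size = NA),
    make_record(7, enrollment = 0L),
    make_record(8, surgeries = list(c("ablation", "2011-06-15"))),  # day 379
    make_record(9, surgeries = list(c("ablation", "2010-07-01"),
                                    c("hepatectomy", "2010-07-01"))),
    make_record(10, diagnosis = "2005-01-01",
                surgeries = list(c("ablation", "2005-02-01"))),
    make_record(11), make_record(12), make_record(13))
  em <- apply_eligibility(make_registry(recs))
  expect_equal(em$log$n_included, 3L)
  expect_equal(em$log$n_included + em$log$n_excluded, 13L)
  counts <- setNames(em$log$counts$n_excluded, em$log$counts$rule)
  expect_equal(counts[["age"]], 2L)
  expect_equal(counts[["missing_diagnosis_date"]], 1L)
  expect_equal(counts[["stage"]], 2L)
  expect_equal(counts[["tumor_size"]], 1L)
  expect_equal(counts[["enrollment"]], 1L)
  expect_equal(counts[["no_surgery_in_window"]], 1L)
  expect_equal(counts[["same_day_procedures"]], 1L)
  expect_equal(counts[["accrual_window"]], 1L)
  # exactly one first-failing reason per excluded record
  expect_equal(nrow(em$log$reasons), 10L)
  expect_false(any(duplicated(em$log$reasons$id)))
})

test_that("exclusions are attributed to the first failing rule in order", {
  # violates both age and tumor size; age comes first in the flowchart
  em <- apply_eligibility(make_registry(list(
    make_record(1, age = 50, size = 80))))
  expect_equal(em$log$reasons$reason, "age")
})

test_that("follow-up arithmetic matches date oracles", {
  crit <- eligibility_criteria()
  # death after ~5.62 years
  fu <- define_followup("2010-01-01", death_date = "2015-08-14",
                        criteria = crit)
  expect_equal(fu$followup_years,
               as.numeric(as.Date("2015-08-14") - as.Date("2010-01-01")) /
                 365.25)
  expect_equal(round(fu$followup_years, 2), 5.62)
  expect_equal(fu$event, 1L)
  expect_equal(fu$censor_reason, "death")
  # surgery on the administrative end date, alive
  fu <- define_followup("2019-12-31", criteria = crit)
  expect_equal(fu$followup_years, 0)
  expect_equal(fu$event, 0L)
  expect_equal(fu$censor_reason, "admin_end")
  # crossover to the other procedure type censors at ~0.50 years
  fu <- define_followup("2012-01-01",
                        second_procedure_date = "2012-06-30",
                        criteria = crit)
  expect_equal(round(fu$followup_years, 2), 0.50)
  expect_equal(fu$event, 0L)
  expect_equal(fu$censor_reason, "second_procedure")
})

test_that("ties at the end of follow-up resolve death first", {
  crit <- eligibility_criteria()
  fu <- define_followup("2015-01-01", death_date = "2016-01-01",
                        second_procedure_date = "2016-01-01",
                        criteria = crit)
  expect_equal(fu$censor_reason, "death")
  expect_equal(fu$event, 1L)
})

test_that("death before surgery is a corrupt record", {
  expect_error(define_followup("2015-01-01", death_date = "2014-12-01",
                               criteria = eligibility_criteria()),
               "corrupt")
})

test_that("intention-to-treat arm and time zero come from the first surgery", {
  recs <- list(
    # multiple ablation sessions: time zero at the first, no censoring
    make_record(1, surgeries = list(c("ablation", "2010-07-01"),
                                    c("ablation", "2010-10-01"))),
    # crossover: ablation first, hepatectomy later -> ablation arm,
    # censored at the hepatectomy
    make_record(2, surgeries = list(c("ablation", "2010-07-01"),
                                    c("hepatectomy", "2011-03-01"))))
  em <- apply_eligibility(make_registry(recs))
  co <- em$cohort
  expect_equal(co$arm, c("ablation", "ablation"))
  expect_equal(co$time_zero, as.Date(c("2010-07-01", "2010-07-01")))
  expect_equal(co$censor_reason, c("admin_end", "second_procedure"))
  expect_equal(co$followup_years[2],
               as.numeric(as.Date("2011-03-01") - as.Date("2010-07-01")) /
                 365.25)
})

test_that("eligibility is idempotent on an already-eligible registry", {
  reg <- generate_registry(registry_config(n = 600, seed = 9))
  em1 <- apply_eligibility(reg)
  keep <- reg$patients$id %in% em1$cohort$id
  reg2 <- structure(list(
    patients = reg$patients[keep, ],
    surgeries = reg$surgeries[reg$surgeries$id %in% em1$cohort$id, ],
    config = NULL), class = "registry")
  em2 <- apply_eligibility(reg2)
  expect_equal(em2$log$n_excluded, 0L)
  expect_equal(em2$cohort$followup_years, em1$cohort$followup_years)
  expect_equal(em2$cohort$arm, em1$cohort$arm)
})

test_that("the small-tumor subgroup is a subset of the main cohort", {
  reg <- generate_registry(registry_config(n = 1000, seed = 10))
  main <- apply_eligibility(reg, eligibility_criteria(max_tumor_mm = 50))
  sub <- apply_eligibility(reg, eligibility_criteria(max_tumor_mm = 30))
  expect_true(all(sub$cohort$id %in% main$cohort$id))
  expect_lt(nrow(sub$cohort), nrow(main$cohort))
})

test_that("exclusion counts are invariant to record order", {
  reg <- generate_registry(registry_config(n = 400, seed = 11))
  em1 <- apply_eligibility(reg)
  set.seed(1)
  perm <- sample(nrow(reg$patients))
  reg2 <- structure(list(patients = reg$patients[perm, ],
                         surgeries = reg$surgeries, config = NULL),
                    class = "registry")
  em2 <- apply_eligibility(reg2)
  expect_equal(em1$log$counts, em2$log$counts)
})

test_that("standardization constants are stored for back-transformation", {
  co <- make_cohort(600, seed = 3)
  std <- attr(co, "standardization")
  expect_equal(co$age_std * std$age_std["sd"] + std$age_std["mean"],
               co$age_at_diagnosis, ignore_attr = TRUE)
  expect_equal(mean(co$size_std), 0, tolerance = 1e-12)
  expect_equal(sd(co$elix_std), 1, tolerance = 1e-12)
})
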