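# Trial emulation: eligibility, treatment arms, time zero and censoring.
#
# The emulated trial enrolls patients 66-100 years old at diagnosis,
# diagnosed inside the accrual window, stage I-II, tumor size at or below
# the configured maximum, receiving partial hepatectomy or ablation within
# one year after diagnosis, with continuous enrollment.  Patients receiving
# both procedure types on the same day are excluded; patients crossing over
# to the other procedure type later are retained and censored at crossover.

# Fixed attrition order; exclusion reasons are attributed to the FIRST
# failing rule, as in a sequential selection flowchart.
EXCLUSION_RULES <- c("malformed", "missing_diagnosis_date", "age",
                     "accrual_window", "stage", "tumor_size", "enrollment",
                     "no_surgery_in_window", "same_day_procedures")

#' Eligibility criteria of the emulated trial
#'
#' @param age_range inclusive age range in years at diagnosis.
#' @param accrual_start,accrual_end inclusive diagnosis-date window.
#' @param stages_allowed allowed stages.
#' @param max_tumor_mm maximum tumor size in mm (50 for the main cohort,
#'   30 for the small-tumor subgroup).
#' @param surgery_window_days first qualifying surgery must occur within
#'   this many days after diagnosis (closed interval).
#' @param study_end administrative censoring date.
#' @return an object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(age_range = c(66, 100),
                                 accrual_start = "2007-01-01",
                                 accrual_end = "2017-12-31",
                                 stages_allowed = c("I", "II"),
                                 max_tumor_mm = 50,
                                 surgery_window_days = 365L,
                                 study_end = "2019-12-31") {
  if (length(age_range) != 2L || age_range[1] > age_range[2])
    stop_field("age_range", "must be an ordered pair")
  check_pos(max_tumor_mm, "max_tumor_mm")
  structure(list(age_range = age_range,
                 accrual_start = as.Date(accrual_start),
                 accrual_end = as.Date(accrual_end),
                 stages_allowed = stages_allowed,
                 max_tumor_mm = max_tumor_mm,
                 surgery_window_days = as.integer(surgery_window_days),
                 study_end = as.Date(study_end)),
            class = "eligibility_criteria")
}

# first failing rule for one patient row (NA = eligible); surgeries is the
# patient's own surgery table, date-sorted
.first_violation <- function(p, surg, criteria) {
  if (!is.na(p$death_date) && nrow(surg) > 0 &&
      p$death_date < min(surg$date)) return("malformed")
  if (is.na(p$diagnosis_date)) return("missing_diagnosis_date")
  if (is.na(p$age_at_diagnosis) || p$age_at_diagnosis < criteria$age_range[1] ||
      p$age_at_diagnosis > criteria$age_range[2]) return("age")
  if (p$diagnosis_date < criteria$accrual_start ||
      p$diagnosis_date > criteria$accrual_end) return("accrual_window")
  if (is.na(p$stage) || !(p$stage %in% criteria$stages_allowed))
    return("stage")
  if (is.na(p$tumor_size_mm) || p$tumor_size_mm > criteria$max_tumor_mm)
    return("tumor_size")
  if (is.na(p$enrollment_ok) || p$enrollment_ok != 1) return("enrollment")
  in_window <- surg$date >= p$diagnosis_date &
    surg$date <= p$diagnosis_date + criteria$surgery_window_days
  if (!any(in_window)) return("no_surgery_in_window")
  qual <- surg[in_window, , drop = FALSE]
  first_day <- min(qual$date)
  if (length(unique(qual$procedure[qual$date == first_day])) > 1L)
    return("same_day_procedures")
  NA_character_
}

#' Follow-up time, event status and censoring reason for one subject
#'
#' Time zero is the date of the first qualifying surgery (the first
#' ablation session when there are several).  Follow-up runs to the first
#' of death, receipt of the other procedure type, or the administrative
#' study end; only death counts as an event.  Ties are broken
#' death > second procedure > administrative end.  Follow-up is reported in
#' years of 365.25 days.
#'
#' @param time_zero date of the first qualifying surgery.
#' @param death_date date of death or `NA`.
#' @param second_procedure_date date of first receipt of the other
#'   procedure type after time zero, or `NA`.
#' @param criteria an [eligibility_criteria()] (supplies `study_end`).
#' @return list with `followup_years`, `event` (0/1) and `censor_reason`
#'   (`"death"`, `"second_procedure"` or `"admin_end"`).
#' @export
define_followup <- function(time_zero, death_date = NA,
                            second_procedure_date = NA, criteria) {
  time_zero <- as.Date(time_zero)
  death_date <- as.Date(death_date)
  second_procedure_date <- as.Date(second_procedure_date)
  if (!is.na(death_date) && death_date < time_zero)
    stop("corrupt record: death precedes surgery", call. = FALSE)
  cand <- c(death = as.numeric(death_date),
            second_procedure = as.numeric(second_procedure_date),
            admin_end = as.numeric(criteria$study_end))
  cand <- cand[!is.na(cand)]
  # names are in tie-break priority order already (death first)
  end <- cand[which.min(cand)]
  reason <- names(end)
  list(followup_years = (end[[1]] - as.numeric(time_zero)) / DAYS_PER_YEAR,
       event = as.integer(reason == "death"),
       censor_reason = reason)
}

#' Apply the emulated trial's eligibility rules to a registry
#'
#' Screens every record against the criteria in a fixed flowchart order,
#' attributes each exclusion to its first failing rule, and builds the
#' analysis cohort: intention-to-treat arm from the first qualifying
#' procedure, time zero at that surgery, follow-up and censoring via
#' [define_followup()].  Records whose death precedes their surgery are
#' rejected with reason `"malformed"` rather than silently dropped.
#' Continuous covariates (age, tumor size, comorbidity score) are
#' standardized with the eligible cohort's mean/SD; the scaling constants
#' are stored in `attr(cohort, "standardization")`.
#'
#' @param registry a `registry` (from [generate_registry()] or
#'   [read_registry()]).
#' @param criteria an [eligibility_criteria()].
#' @return list with `cohort` (data frame of analysis subjects, one row per
#'   patient, raw and standardized covariates) and `log` (an
#'   `exclusion_log` with per-rule counts in rule order and per-record
#'   reasons).
#' @export
apply_eligibility <- function(registry, criteria = eligibility_criteria()) {
  patients <- registry$patients
  surgeries <- registry$surgeries
  n <- nrow(patients)
  reason <- character(n)
  surg_by_id <- split(surgeries, surgeries$id)

  for (r in seq_len(n)) {
    p <- patients[r, ]
    surg <- surg_by_id[[as.character(p$id)]]
    if (is.null(surg)) surg <- surgeries[0, ]
    v <- .first_violation(p, surg, criteria)
    reason[r] <- if (is.na(v)) "" else v
  }

  keep <- reason == ""
  counts <- table(factor(reason[reason != ""], levels = EXCLUSION_RULES))
  log <- structure(list(
    n_input = n, n_included = sum(keep), n_excluded = sum(!keep),
    counts = as.data.frame(counts, responseName = "n_excluded",
                           stringsAsFactors = FALSE) |>
      setNames(c("rule", "n_excluded")),
    reasons = data.frame(id = patients$id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)),
    class = "exclusion_log")

  elig <- patients[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(elig)), function(r) {
    p <- elig[r, ]
    surg <- surg_by_id[[as.character(p$id)]]
    in_window <- surg$date >= p$diagnosis_date &
      surg$date <= p$diagnosis_date + criteria$surgery_window_days
    qual <- surg[in_window, , drop = FALSE]
    t0 <- min(qual$date)
    arm <- qual$procedure[qual$date == t0][1]
    other <- surg[surg$procedure != arm & surg$date > t0, , drop = FALSE]
    second <- if (nrow(other)) min(other$date) else as.Date(NA)
    fu <- define_followup(t0, p$death_date, second, criteria)
    data.frame(id = p$id, arm = arm, time_zero = t0,
               followup_years = fu$followup_years, event = fu$event,
               censor_reason = fu$censor_reason, stringsAsFactors = FALSE)
  })
  fu_df <- do.call(rbind, rows)

  cohort <- cbind(fu_df,
                  elig[, c("age_at_diagnosis", "female", "white", "married",
                           "stage", "tumor_size_mm", "elixhauser_score",
                           LIVER_FLAGS)])
  cohort$stage2 <- as.integer(cohort$stage == "II")
  cohort$ablation <- as.integer(cohort$arm == "ablation")
  std <- list()
  std_map <- c(age_std = "age_at_diagnosis", size_std = "tumor_size_mm",
               elix_std = "elixhauser_score")
  for (out in names(std_map)) {
    raw <- cohort[[std_map[[out]]]]
    m <- mean(raw); s <- sd(raw)
    cohort[[out]] <- (raw - m) / s
    std[[out]] <- c(mean = m, sd = s)
  }
  rownames(cohort) <- NULL
  attr(cohort, "standardization") <- std
  attr(cohort, "criteria") <- criteria
  list(cohort = cohort, log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat(sprintf("Eligibility screening: %d in, %d included, %d excluded\n",
              x$n_input, x$n_included, x$n_excluded))
  print(x$counts[x$counts$n_excluded > 0, ], row.names = FALSE)
  invisible(x)
}
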