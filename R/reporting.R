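# Descriptive statistics, unweighted survival comparison and the
# frequentist comparator.  Kaplan-Meier curves, the log-rank test and the
# comparator's Weibull fit are delegated to the survival package; the
# package's own tests check them against hand-computed and permutation
# oracles.

#' Kaplan-Meier survival curves by arm
#'
#' Product-limit estimator per arm, with the median survival time (first
#' time at which the survival probability drops to 0.5 or below; absent
#' when the curve never reaches 0.5).
#'
#' @param times follow-up times (>= 0).
#' @param events 0/1 event indicators.
#' @param arm arm labels (two groups, or one).
#' @return object of class `km_curve`: per-arm list of `time`, `surv`,
#'   `n_risk` step function values and `median` survival.
#' @export
km_estimate <- function(times, events, arm) {
  stopifnot(length(times) == length(events),
            length(times) == length(arm), all(times >= 0))
  if (length(times) == 0L) stop("empty arm", call. = FALSE)
  arms <- split(seq_along(times), arm)
  curves <- lapply(arms, function(idx) {
    fit <- survival::survfit(
      survival::Surv(times[idx], events[idx]) ~ 1)
    med <- fit$time[fit$surv <= 0.5][1]   # first time S(t) <= 0.5
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n = length(idx), events = sum(events[idx]),
         median = if (length(med) == 0L || is.na(med)) NA_real_ else med)
  })
  structure(curves, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate:\n")
  for (nm in names(x))
    cat(sprintf("  %s: n = %d, events = %d, median survival = %s years\n",
                nm, x[[nm]]$n, x[[nm]]$events,
                if (is.na(x[[nm]]$median)) "not reached"
                else sprintf("%.1f", x[[nm]]$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank comparison of two arms with simultaneous
#' risk-set accounting for ties.
#'
#' @inheritParams km_estimate
#' @return list with `statistic` (chi-square), `df` and `p_value`.
#' @export
logrank_test <- function(times, events, arm) {
  if (length(unique(arm)) != 2L)
    stop("log-rank test needs exactly two arms", call. = FALSE)
  if (sum(events) < 1) stop("no events observed", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ arm)
  list(statistic = fit$chisq, df = 1L,
       p_value = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Demographics and comorbidity summary table
#'
#' Per-arm and total summaries: `count (pct%)` for binary covariates (one
#' decimal place) and `mean (sd)` for continuous ones, with descriptive
#' group-comparison p-values (chi-square for binaries, Welch t-test for
#' continuous).
#'
#' @param cohort analysis cohort (raw-scale covariate columns).
#' @param binary,continuous covariate columns to summarize.
#' @return data frame of class `descriptive_table`.
#' @export
descriptive_table <- function(cohort,
                              binary = c("female", "white", "married",
                                         "stage2", LIVER_FLAGS),
                              continuous = c("age_at_diagnosis",
                                             "tumor_size_mm",
                                             "elixhauser_score")) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  g1 <- cohort$arm == "hepatectomy"
  n1 <- sum(g1); n0 <- sum(!g1); n <- nrow(cohort)
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    p <- tryCatch(t.test(x[g1], x[!g1])$p.value, error = function(e) NA)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      hepatectomy = sprintf("%.1f (%.2f)", mean(x[g1]), sd(x[g1])),
      ablation = sprintf("%.1f (%.2f)", mean(x[!g1]), sd(x[!g1])),
      total = sprintf("%.1f (%.2f)", mean(x), sd(x)),
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in binary) {
    x <- cohort[[v]]
    tab <- table(factor(x, levels = 0:1), factor(g1, levels = c(TRUE, FALSE)))
    p <- tryCatch(suppressWarnings(chisq.test(tab)$p.value),
                  error = function(e) NA)
    rows[[v]] <- data.frame(
      variable = v, type = "binary",
      hepatectomy = fmt_count_pct(sum(x[g1]), n1),
      ablation = fmt_count_pct(sum(x[!g1]), n0),
      total = fmt_count_pct(sum(x), n),
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- c(hepatectomy = n1, ablation = n0, total = n)
  class(out) <- c("descriptive_table", "data.frame")
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("Cohort: hepatectomy n = %d, ablation n = %d, total n = %d\n",
              n[1], n[2], n[3]))
  y <- x; y$p_value <- signif(y$p_value, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Frequentist comparator analysis
#'
#' The standard single-imputation IPTW pipeline used as a baseline: one
#' maximum-likelihood logistic propensity fit, one stabilized truncated
#' weight vector, and a weighted maximum-likelihood Weibull fit
#' ([survival::survreg()]) transformed to the log-hazard scale
#' (`beta = -beta_AFT / scale`), with delta-method Wald intervals.
#'
#' @param cohort analysis cohort.
#' @param truncate_pct weight truncation percentile.
#' @param level confidence level.
#' @param weights optional fixed weight vector overriding the propensity
#'   step (e.g. unit weights for an unweighted fit).
#' @return data frame of class `comparator_fit` with log-HR estimates,
#'   standard errors, Wald confidence limits and HR transforms; attribute
#'   `converged`.
#' @export
frequentist_comparator <- function(cohort, truncate_pct = 99.5,
                                   level = 0.95, weights = NULL) {
  if (is.null(weights)) {
    Xp <- ps_design(cohort)
    ml <- suppressWarnings(glm.fit(Xp, cohort$ablation,
                                   family = binomial()))
    scores <- plogis(drop(Xp %*% coef(ml)))
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
    weights <- compute_stabilized_weights(scores, cohort$ablation,
                                          truncate_pct)$weights
  }
  X <- outcome_design(cohort)
  t_pos <- pmax(cohort$followup_years, 1e-6)
  fit <- tryCatch(
    survival::survreg(survival::Surv(t_pos, cohort$event) ~ X,
                      weights = weights, dist = "weibull"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- data.frame(parameter = character(), estimate = numeric())
    attr(out, "converged") <- FALSE
    attr(out, "message") <- conditionMessage(fit)
    class(out) <- c("comparator_fit", "data.frame")
    return(out)
  }
  sigma <- fit$scale
  k <- 1 / sigma
  b_aft <- coef(fit)
  V <- vcov(fit)                        # includes Log(scale) as last row/col
  p <- length(b_aft)
  est <- c(shape = k, log_lambda = -k * b_aft[1], -k * b_aft[-1])
  names(est)[-(1:2)] <- colnames(X)
  # delta method: g_j = -b_j / sigma, with theta = (b, log sigma);
  # dg/db_j = -1/sigma, dg/dlogsigma = b_j/sigma
  se <- vapply(seq_len(p), function(j) {
    grad <- numeric(p + 1)
    grad[j] <- -1 / sigma
    grad[p + 1] <- b_aft[j] / sigma
    sqrt(drop(t(grad) %*% V %*% grad))
  }, numeric(1))
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(parameter = names(est), estimate = unname(est),
                    se = c(NA_real_, se),   # shape SE not reported
                    stringsAsFactors = FALSE)
  out$ci_low <- out$estimate - z * out$se
  out$ci_high <- out$estimate + z * out$se
  is_coef <- !(out$parameter %in% c("shape", "log_lambda"))
  out$hr <- ifelse(is_coef, exp(out$estimate), NA_real_)
  out$hr_low <- ifelse(is_coef, exp(out$ci_low), NA_real_)
  out$hr_high <- ifelse(is_coef, exp(out$ci_high), NA_real_)
  attr(out, "converged") <- TRUE
  class(out) <- c("comparator_fit", "data.frame")
  out
}

#' @export
print.comparator_fit <- function(x, digits = 2, ...) {
  if (!isTRUE(attr(x, "converged"))) {
    cat("Frequentist comparator: did not converge (",
        attr(x, "message"), ")\n", sep = "")
    return(invisible(x))
  }
  cat("Frequentist IPTW Weibull comparator (log-hazard scale):\n")
  y <- x
  for (cl in c("estimate", "se", "ci_low", "ci_high", "hr", "hr_low",
               "hr_high"))
    y[[cl]] <- round(y[[cl]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
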