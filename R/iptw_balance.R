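# Stabilized, truncated IPT weights and covariate balance.

#' Stabilized, truncated inverse-probability-of-treatment weights
#'
#' Raw weights are `1/e_i` for the ablation arm and `1/(1 - e_i)` for the
#' hepatectomy arm, where `e_i = P(ablation | x_i)`.  Stabilization
#' multiplies by the marginal arm proportion, preserving the group size
#' ratio.  Any stabilized weight above the upper `truncate_pct` percentile
#' of the whole-cohort weight distribution (computed within this weight
#' set) is set to that percentile value.
#'
#' @param scores propensity scores in the open interval (0, 1).
#' @param arms 0/1 ablation indicator (or a character/factor vector where
#'   `"ablation"` marks the ablation arm).
#' @param truncate_pct upper truncation percentile (default 99.5); `NULL`
#'   disables truncation.
#' @param stabilize multiply by marginal arm proportions (default TRUE).
#' @param draw_index bookkeeping index of the propensity draw.
#' @return an object of class `weight_set`: positive `weights`, the
#'   `truncation_threshold` used, and flags.
#' @export
compute_stabilized_weights <- function(scores, arms, truncate_pct = 99.5,
                                       stabilize = TRUE, draw_index = NA) {
  if (any(scores <= 0 | scores >= 1))
    stop("propensity scores must lie strictly inside (0, 1)", call. = FALSE)
  a <- if (is.numeric(arms)) as.integer(arms)
       else as.integer(as.character(arms) == "ablation")
  if (length(a) != length(scores))
    stop("scores and arms have different lengths", call. = FALSE)
  w <- ifelse(a == 1, 1 / scores, 1 / (1 - scores))
  if (stabilize) {
    p1 <- mean(a)
    w <- ifelse(a == 1, p1, 1 - p1) * w
  }
  threshold <- NA_real_
  if (!is.null(truncate_pct)) {
    threshold <- quantile(w, truncate_pct / 100, names = FALSE)
    w <- pmin(w, threshold)
  }
  structure(list(weights = w, truncation_threshold = threshold,
                 stabilized = stabilize, truncate_pct = truncate_pct,
                 draw_index = draw_index),
            class = "weight_set")
}

#' Weighted standardized mean differences
#'
#' For each covariate, computes `d_j = |xbar_1 - xbar_0| /
#' sqrt((s_1^2 + s_0^2) / 2)` with weighted arm means and
#' frequency-weighted arm variances `sum(w (x - xbar)^2) / sum(w)`.
#' Unit weights reproduce the unweighted SMD.  If the pooled variance is
#' zero, the SMD is 0 when the arm means agree and `Inf` otherwise.
#'
#' @param covariates data frame or matrix of covariate columns.
#' @param treated 0/1 arm indicator.
#' @param weights positive weights (default: unit weights).
#' @return named numeric vector of absolute SMDs.
#' @export
weighted_smd <- function(covariates, treated, weights = NULL) {
  X <- as.matrix(covariates)
  n <- nrow(X)
  w <- weights %||% rep(1, n)
  if (inherits(w, "weight_set")) w <- w$weights
  stopifnot(length(treated) == n, length(w) == n, all(w > 0))
  t1 <- treated == 1
  vapply(colnames(X) %||% seq_len(ncol(X)), function(j) {
    x <- X[, j]
    m1 <- sum(w[t1] * x[t1]) / sum(w[t1])
    m0 <- sum(w[!t1] * x[!t1]) / sum(w[!t1])
    v1 <- sum(w[t1] * (x[t1] - m1)^2) / sum(w[t1])
    v0 <- sum(w[!t1] * (x[!t1] - m0)^2) / sum(w[!t1])
    pooled <- (v1 + v0) / 2
    if (pooled == 0) return(if (m1 == m0) 0 else Inf)
    abs(m1 - m0) / sqrt(pooled)
  }, numeric(1))
}

#' Covariate balance before and after weighting
#'
#' Computes the unweighted SMD and, for each retained propensity draw, the
#' SMD under that draw's stabilized truncated weights; weighted SMDs are
#' averaged over the weight sets.
#'
#' @param cohort analysis cohort (needs the covariate columns and
#'   `ablation`).
#' @param ps a `ps_draws` object, a list of `weight_set`s, or a numeric
#'   matrix of scores (draws x n).
#' @param covariates covariate columns to assess (default: the propensity
#'   covariate set).
#' @param truncate_pct passed to [compute_stabilized_weights()] when `ps`
#'   supplies scores.
#' @return data frame of class `balance_table` with columns `covariate`,
#'   `smd_unweighted`, `smd_weighted` (mean over weight sets).
#' @export
balance_table <- function(cohort, ps, covariates = PS_COVARIATES,
                          truncate_pct = 99.5) {
  treated <- cohort$ablation
  covs <- cohort[, covariates, drop = FALSE]
  before <- weighted_smd(covs, treated)

  weight_sets <- if (inherits(ps, "ps_draws")) {
    lapply(seq_len(nrow(ps$scores)), function(d)
      compute_stabilized_weights(ps$scores[d, ], treated, truncate_pct,
                                 draw_index = d))
  } else if (is.matrix(ps)) {
    lapply(seq_len(nrow(ps)), function(d)
      compute_stabilized_weights(ps[d, ], treated, truncate_pct,
                                 draw_index = d))
  } else ps
  smds <- sapply(weight_sets, function(ws)
    weighted_smd(covs, treated, ws$weights))
  out <- data.frame(covariate = names(before),
                    smd_unweighted = unname(before),
                    smd_weighted = rowMeans(smds),
                    stringsAsFactors = FALSE)
  class(out) <- c("balance_table", "data.frame")
  out
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  cat("Covariate balance (absolute SMD):\n")
  y <- x
  y$smd_unweighted <- round(y$smd_unweighted, digits)
  y$smd_weighted <- round(y$smd_weighted, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
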