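# Weighted Bayesian Weibull outcome model, posterior pooling and
# Gelman-Rubin diagnostics.
#
# The Weibull model is parameterized on the proportional-hazards scale,
# h(t | x) = k * lambda * t^(k-1) * exp(x'beta); for the Weibull family
# this is equivalent to the accelerated-failure-time form via
# beta_AFT = -beta / k, so priors stated on log hazard ratios apply
# directly.  Weights enter as frequency-style multipliers of the
# per-subject log-likelihood terms (a pseudo-posterior).

outcome_design <- function(cohort, covariates = OUTCOME_COVARIATES) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("cohort lacks outcome covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- cbind(ablation = cohort$ablation,
             as.matrix(cohort[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Weighted Weibull proportional-hazards log-likelihood
#'
#' `sum_i w_i * [ delta_i * (log k + log lambda + (k-1) log t_i + x_i'beta)
#'               - lambda * t_i^k * exp(x_i'beta) ]`.
#' Zero-time censored records contribute nothing; doubling a subject's
#' weight equals duplicating the subject.  A non-positive shape returns
#' `-Inf` (rejected by the sampler) rather than raising an error.
#'
#' @param params list or named vector with `shape` (k), `log_lambda` and
#'   `beta` (named coefficient vector aligned with the design columns).
#' @param time follow-up times in years (>= 0; > 0 wherever `event` is 1).
#' @param event 0/1 event indicators.
#' @param X design matrix (no intercept column; `log_lambda` is the
#'   intercept on the log-rate scale).
#' @param weights positive subject weights (default unit).
#' @return the weighted log-likelihood (scalar).
#' @export
weighted_weibull_loglik <- function(params, time, event, X,
                                    weights = NULL) {
  k <- if (is.list(params)) params$shape else params[["shape"]]
  log_lambda <- if (is.list(params)) params$log_lambda
                else params[["log_lambda"]]
  beta <- if (is.list(params)) params$beta
          else params[setdiff(names(params), c("shape", "log_lambda"))]
  if (!is.finite(k) || k <= 0) return(-Inf)
  w <- weights %||% rep(1, length(time))
  eta <- if (length(beta)) drop(X %*% beta) else 0
  lambda <- exp(log_lambda)
  d <- event == 1
  ll_event <- sum(w[d] * (log(k) + log_lambda + (k - 1) * log(time[d]) +
                            (if (length(beta)) eta[d] else 0)))
  ll_cum <- -sum(w * lambda * time^k * exp(eta))
  ll_event + ll_cum
}

#' Fit the weighted Bayesian Weibull posterior for one pseudo-population
#'
#' Samples `(log k, log lambda, beta)` by adaptive random-walk Metropolis
#' from the weighted likelihood times the priors: treatment log HR
#' `~ N(treatment_mean, treatment_sd^2)` (the literature-elicited prior),
#' each covariate and the log baseline rate `~ N(0, covariate_prior_sd^2)`,
#' and the shape `k ~ Exponential(shape_prior_rate)` sampled on the log
#' scale with the Jacobian term.  The chain is initialized at a weighted
#' maximum-likelihood fit ([survival::survreg()]) when available.
#'
#' @param cohort analysis cohort with `followup_years`, `event`,
#'   `ablation` and the outcome covariates (marital status included).
#' @param weights a `weight_set` or positive numeric vector (default unit
#'   weights).
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()]; the outcome protocol is 20,000
#'   iterations with 10,000 burn-in, no thinning.
#' @param covariates outcome covariate columns.
#' @return matrix of retained draws (rows) with columns `shape`,
#'   `log_lambda`, `ablation`, then the covariates; attribute `acceptance`.
#' @export
fit_outcome_posterior <- function(cohort, weights = NULL,
                                  prior = prior_spec(),
                                  mcmc = mcmc_config(iterations = 20000L,
                                                     burn_in = 10000L,
                                                     thin = 1L),
                                  covariates = OUTCOME_COVARIATES) {
  X <- outcome_design(cohort, covariates)
  time <- cohort$followup_years
  event <- cohort$event
  w <- weights %||% rep(1, nrow(X))
  if (inherits(w, "weight_set")) w <- w$weights
  if (length(w) != nrow(X))
    stop("weights not aligned with the cohort", call. = FALSE)
  if (all(event == 0))
    warning("all records censored: the posterior is prior-dominated")
  p <- ncol(X)

  prior_sd <- c(prior$treatment_sd, rep(prior$covariate_prior_sd, p - 1))
  prior_mean <- c(prior$treatment_mean, rep(0, p - 1))
  rate <- prior$shape_prior_rate
  cov_sd <- prior$covariate_prior_sd
  d <- event == 1
  # a death on the day of surgery contributes half a day of follow-up;
  # zero-time censored records keep time 0 (they contribute nothing)
  time[d] <- pmax(time[d], 0.5 / DAYS_PER_YEAR)
  wd <- w[d]; log_td <- log(time[d]); td <- time[d]
  Xd <- X[d, , drop = FALSE]

  # theta = (log k, log lambda, beta); exponential prior on k with
  # log-scale Jacobian: log p(log k) = log(rate) - rate*k + log k
  log_post <- function(theta) {
    k <- exp(theta[1]); log_lambda <- theta[2]
    beta <- theta[-(1:2)]
    eta <- drop(X %*% beta)
    ll <- sum(wd * (log(k) + log_lambda + (k - 1) * log_td +
                      drop(Xd %*% beta))) -
      exp(log_lambda) * sum(w * time^k * exp(eta))
    if (!is.finite(ll)) return(-Inf)
    ll - rate * k + theta[1] -
      log_lambda^2 / (2 * cov_sd^2) -
      sum((beta - prior_mean)^2 / (2 * prior_sd^2))
  }

  init <- c(0, log(max(mean(event), 0.05) / max(mean(time), 1e-6)),
            numeric(p))
  ml <- tryCatch({
    t_pos <- pmax(time, 1e-6)
    sr <- suppressWarnings(
      survival::survreg(survival::Surv(t_pos, event) ~ X, weights = w,
                        dist = "weibull",
                        control = survival::survreg.control(maxiter = 100)))
    k_hat <- 1 / sr$scale
    b_aft <- coef(sr)
    c(log(k_hat), -k_hat * b_aft[1], -k_hat * b_aft[-1])
  }, error = function(e) NULL)
  if (!is.null(ml) && all(is.finite(ml)) && max(abs(ml)) < 50) init <- ml

  seed <- mcmc$seed %||% 1L
  prop_cov <- curvature_cov(log_post, init)
  fit <- rwm_sample(log_post, init, mcmc$iterations, mcmc$burn_in,
                    mcmc$target_acceptance, seed = derive_seed(seed, 17L),
                    init_cov = prop_cov)
  chain <- fit$chain[(mcmc$burn_in + 1):mcmc$iterations, , drop = FALSE]
  if (mcmc$thin > 1L) chain <- thin_draws(chain, 0L, mcmc$thin)
  draws <- cbind(exp(chain[, 1]), chain[, -1, drop = FALSE])
  colnames(draws) <- c("shape", "log_lambda", colnames(X))
  attr(draws, "acceptance") <- fit$acceptance
  draws
}

#' Pool per-pseudo-population posterior draws
#'
#' Concatenates the per-weight-set posterior samples with no reweighting;
#' the pooled sample is the mixture over pseudo-populations that carries
#' the propensity-score uncertainty into the treatment-effect posterior.
#' At the full protocol scale (500 weight sets x 10,000 retained draws)
#' the pooled sample holds 5,000,000 draws.
#'
#' @param draws_list list of draw matrices from [fit_outcome_posterior()].
#' @return an `outcome_draws` matrix with a `set` provenance attribute.
#' @export
pool_posteriors <- function(draws_list) {
  if (!length(draws_list)) stop("no draws to pool", call. = FALSE)
  cn <- colnames(draws_list[[1]])
  for (d in draws_list)
    if (!identical(colnames(d), cn))
      stop("mismatched parameter names across weight sets", call. = FALSE)
  pooled <- do.call(rbind, draws_list)
  attr(pooled, "set") <- rep(seq_along(draws_list),
                             vapply(draws_list, nrow, integer(1)))
  class(pooled) <- c("outcome_draws", class(pooled))
  pooled
}

#' Summarize a posterior sample
#'
#' Per-parameter posterior mean, median and equal-tailed 95% credible
#' interval; coefficient rows additionally carry hazard-ratio-scale
#' summaries (`exp` of the log-scale figures) and a significance flag (the
#' log-scale interval excludes 0).  A log HR of 0.30 with interval
#' (0.13, 0.47) prints as HR 1.35 (1.14, 1.60) at two decimals.
#'
#' @param draws an `outcome_draws` matrix (or any draws matrix / vector).
#' @param level credible level (default 0.95).
#' @return data frame of class `posterior_summary`.
#' @export
summarize_posterior <- function(draws, level = 0.95) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "param"))
  if (nrow(draws) == 0L) stop("empty posterior sample", call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  out <- data.frame(parameter = colnames(draws),
                    mean = colMeans(draws),
                    median = qs[2, ], cri_low = qs[1, ], cri_high = qs[3, ],
                    stringsAsFactors = FALSE)
  is_coef <- !(out$parameter %in% c("shape", "log_lambda"))
  out$hr <- ifelse(is_coef, exp(out$median), NA_real_)
  out$hr_low <- ifelse(is_coef, exp(out$cri_low), NA_real_)
  out$hr_high <- ifelse(is_coef, exp(out$cri_high), NA_real_)
  out$significant <- is_coef & (out$cri_low > 0 | out$cri_high < 0)
  rownames(out) <- NULL
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, digits = 2, ...) {
  y <- x
  for (cl in c("mean", "median", "cri_low", "cri_high", "hr", "hr_low",
               "hr_high"))
    y[[cl]] <- round(y[[cl]], digits)
  cat("Posterior summary (equal-tailed credible intervals):\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF from `m >= 2` chains of equal length `n`:
#' with within-chain variance `W` (mean of per-chain variances) and
#' between-chain variance `B = n * var(chain means)`,
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.  Identical chains give
#' `sqrt((n-1)/n)`.
#'
#' @param chains list of draw matrices (iterations x parameters) or
#'   vectors, all the same length.
#' @return data frame of class `psrf_report` with one row per parameter;
#'   attributes `chains` and `chain_length`.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2L) stop("need at least two chains", call. = FALSE)
  chains <- lapply(chains, function(ch)
    if (is.null(dim(ch))) matrix(ch, ncol = 1,
                                 dimnames = list(NULL, "param")) else ch)
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1L) stop("chains have unequal lengths", call. = FALSE)
  if (n < 2L) stop("chains must have length >= 2", call. = FALSE)
  params <- colnames(chains[[1]]) %||% paste0("p", seq_len(ncol(chains[[1]])))
  psrf <- vapply(seq_along(params), function(j) {
    draws <- sapply(chains, function(ch) ch[, j])    # n x m
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  out <- data.frame(parameter = params, psrf = psrf,
                    stringsAsFactors = FALSE)
  attr(out, "chains") <- length(chains)
  attr(out, "chain_length") <- n
  class(out) <- c("psrf_report", "data.frame")
  out
}

#' @export
print.psrf_report <- function(x, digits = 4, ...) {
  cat(sprintf("Gelman-Rubin PSRF (%d chains of length %d):\n",
              attr(x, "chains"), attr(x, "chain_length")))
  y <- x; y$psrf <- round(y$psrf, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
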