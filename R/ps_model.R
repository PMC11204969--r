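# Bayesian logistic propensity-score model.
#
# Posterior: product of Bernoulli likelihoods for treatment assignment
# times independent normal(0, variance 100) priors on every coefficient,
# sampled with the package's adaptive random-walk Metropolis sampler.

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

ps_design <- function(cohort, covariates = PS_COVARIATES) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop("cohort lacks propensity covariates: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(intercept = 1, as.matrix(cohort[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Fit the Bayesian logistic propensity-score posterior
#'
#' Samples the posterior of the treatment-assignment model
#' `A_i ~ Bernoulli(logit^{-1}(x_i' gamma))` with independent
#' normal(0, variance 100) priors on all coefficients, using an adaptive
#' Gaussian random-walk Metropolis sampler initialized at the
#' maximum-likelihood estimate.  The production chain is thinned to the
#' retained propensity-score draws; with the default 10,000 iterations,
#' 5,000 burn-in and thinning by 10, exactly 500 sets of propensity scores
#' are retained.  When `mcmc$chains > 1`, additional independently seeded
#' chains are run (initialized with jitter around the ML estimate) and kept
#' for Gelman-Rubin diagnostics; the first chain supplies the scores.
#'
#' @param cohort analysis cohort from [apply_eligibility()] (or any data
#'   frame with an `ablation` 0/1 column and the propensity covariates).
#' @param prior a [prior_spec()]; only `ps_prior_sd` is used here.
#' @param mcmc an [mcmc_config()].
#' @param covariates character vector of covariate columns (marital status
#'   is deliberately absent from the default propensity set).
#' @return an object of class `ps_draws`: retained coefficient draws
#'   `gamma` (draws x p), the score matrix `scores` (draws x n) with every
#'   entry strictly inside (0, 1), per-chain unthinned retained draws in
#'   `chains`, and the post-burn-in `acceptance` rate.
#' @export
fit_ps_posterior <- function(cohort, prior = prior_spec(),
                             mcmc = mcmc_config(),
                             covariates = PS_COVARIATES) {
  X <- ps_design(cohort, covariates)
  A <- cohort$ablation
  if (is.null(A)) stop("cohort lacks an 'ablation' treatment column",
                       call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient propensity design matrix", call. = FALSE)
  p <- ncol(X)
  prior_var <- prior$ps_prior_sd^2

  log_post <- function(gamma) {
    eta <- drop(X %*% gamma)
    sum(A * eta) - sum(log1pexp(eta)) - sum(gamma^2) / (2 * prior_var)
  }

  ml <- tryCatch(
    suppressWarnings(glm.fit(X, A, family = binomial())),
    error = function(e) NULL)
  init <- numeric(p)
  if (!is.null(ml) && all(is.finite(coef(ml)))) {
    if (!ml$converged || max(abs(coef(ml))) > 20)
      warning("possible complete separation in the treatment model; ",
              "the normal prior regularizes the posterior")
    if (max(abs(coef(ml))) <= 20) init <- coef(ml)
  }

  seed <- mcmc$seed %||% 1L
  prop_cov <- curvature_cov(log_post, init)
  init_sd <- if (is.null(prop_cov)) rep(0.1, p) else sqrt(diag(prop_cov))
  chains <- vector("list", mcmc$chains)
  acc <- NA_real_
  for (ch in seq_len(mcmc$chains)) {
    chain_seed <- derive_seed(seed, ch)
    init_ch <- init
    if (ch > 1L) {                       # over-dispersed starts for PSRF
      set.seed(derive_seed(seed, 1000L + ch))
      init_ch <- init + rnorm(p, 0, 2 * init_sd)
    }
    fit <- rwm_sample(log_post, init_ch, mcmc$iterations, mcmc$burn_in,
                      mcmc$target_acceptance, seed = chain_seed,
                      init_cov = prop_cov)
    if (ch == 1L) acc <- fit$acceptance
    chains[[ch]] <- fit$chain[(mcmc$burn_in + 1):mcmc$iterations, ,
                              drop = FALSE]
    colnames(chains[[ch]]) <- colnames(X)
  }

  gamma <- thin_draws(chains[[1]], 0L, mcmc$thin)
  scores <- plogis(gamma %*% t(X))
  structure(list(gamma = gamma, scores = scores, chains = chains,
                 acceptance = acc, covariates = colnames(X),
                 mcmc = mcmc, n = nrow(X)),
            class = "ps_draws")
}

#' @export
print.ps_draws <- function(x, ...) {
  cat(sprintf(paste0("Bayesian propensity-score posterior: %d retained",
                     " draws x %d subjects\n"),
              nrow(x$gamma), x$n))
  cat(sprintf("chains: %d, post-burn-in acceptance (chain 1): %.3f\n",
              length(x$chains), x$acceptance))
  pm <- colMeans(x$gamma)
  print(round(pm, 3))
  invisible(x)
}
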