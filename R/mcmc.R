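#' MCMC sampler settings
#'
#' Settings shared by the propensity-score and outcome samplers.  Defaults
#' follow the analysis protocol: 10,000 iterations with a 5,000-iteration
#' burn-in and thinning to every 10th draw for the propensity model (500
#' retained propensity-score sets); the outcome model uses 20,000/10,000
#' without thinning.  Five independent chains are used for convergence
#' diagnostics; production runs use one chain.
#'
#' @param iterations total MCMC iterations (including burn-in).
#' @param burn_in iterations discarded as burn-in; must be < `iterations`.
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param chains number of independent chains (>= 1).
#' @param target_acceptance target acceptance rate for the adaptive
#'   random-walk proposal (the 0.234 multivariate optimum by default).
#' @param seed integer seed for the sampler's random stream.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 10000L, burn_in = 5000L, thin = 10L,
                        chains = 1L, target_acceptance = 0.234,
                        seed = NULL) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (iterations <= 0L) stop_field("iterations", "must be positive")
  if (burn_in < 0L || burn_in >= iterations)
    stop_field("burn_in", "must satisfy 0 <= burn_in < iterations")
  if (thin < 1L) stop_field("thin", "must be >= 1")
  if (chains < 1L) stop_field("chains", "must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = as.integer(chains),
                 target_acceptance = target_acceptance, seed = seed),
            class = "mcmc_config")
}

#' Thin an MCMC chain
#'
#' Discards the burn-in and keeps every `thin`-th subsequent draw: indices
#' `burn_in + thin, burn_in + 2*thin, ...` (1-based).  A 10,000-iteration
#' chain with 5,000 burn-in thinned by 10 retains exactly 500 draws.
#'
#' @param raw_chain matrix (iterations x parameters) or vector of draws.
#' @param burn_in number of leading iterations to discard.
#' @param thin keep every `thin`-th draw after burn-in.
#' @return the retained draws, same column structure as the input.
#' @export
thin_draws <- function(raw_chain, burn_in, thin) {
  vec <- is.null(dim(raw_chain))
  len <- if (vec) length(raw_chain) else nrow(raw_chain)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (thin < 1L) stop_field("thin", "must be >= 1")
  if (burn_in >= len)
    stop_field("burn_in", "must be smaller than the chain length")
  if (len < burn_in + thin)
    stop("chain too short: need length >= burn_in + thin", call. = FALSE)
  keep <- seq.int(burn_in + thin, len, by = thin)
  if (vec) raw_chain[keep] else raw_chain[keep, , drop = FALSE]
}

# Adaptive Gaussian random-walk Metropolis sampler.
#
# Proposal covariance is adapted during burn-in (Haario-style empirical
# covariance plus Robbins-Monro tuning of a global scale toward the target
# acceptance rate) and frozen at the end of burn-in, so the post-burn-in
# chain is a valid time-homogeneous Metropolis chain.  Returns the full
# chain plus the post-burn acceptance rate; thinning is applied by callers
# via thin_draws().
rwm_sample <- function(log_post, init, iterations, burn_in,
                       target_acceptance = 0.234, seed = NULL,
                       init_cov = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  chain <- matrix(NA_real_, iterations, d)
  x <- as.numeric(init)
  lp <- log_post(x)
  if (!is.finite(lp)) { x <- numeric(d); lp <- log_post(x) }
  if (!is.finite(lp)) stop("log posterior not finite at the initial value")

  log_scale <- log(2.38^2 / d)
  run_mean <- x
  run_cov <- if (is.null(init_cov)) diag(d) * 0.01 else init_cov
  chol_prop <- tryCatch(
    chol(exp(log_scale) * (run_cov + 1e-8 * diag(d))),
    error = function(e) chol(exp(log_scale) * diag(d) * 0.01))
  accept_post <- 0L

  for (i in seq_len(iterations)) {
    prop <- x + drop(crossprod(chol_prop, rnorm(d)))
    lp_prop <- log_post(prop)
    log_alpha <- lp_prop - lp
    accepted <- is.finite(lp_prop) && log(runif(1)) < log_alpha
    if (accepted) { x <- prop; lp <- lp_prop }
    chain[i, ] <- x
    if (i > burn_in && accepted) accept_post <- accept_post + 1L

    if (i <= burn_in) {
      # Robbins-Monro step on the global scale, vanishing gain
      alpha <- min(1, exp(log_alpha))
      if (!is.finite(alpha)) alpha <- 0
      log_scale <- log_scale + (alpha - target_acceptance) / i^0.6
      # running empirical covariance of the chain so far
      # blend the running empirical covariance into the initial curvature
      # estimate so early adaptation is stable
      delta <- x - run_mean
      run_mean <- run_mean + delta / i
      run_cov <- run_cov * (i - 1 + 50) / (i + 50) +
        tcrossprod(delta, x - run_mean) / (i + 50)
      if (i %% 50L == 0L || i == burn_in) {
        sigma <- exp(log_scale) * (run_cov + 1e-8 * diag(d))
        ch <- tryCatch(chol(sigma), error = function(e) NULL)
        if (!is.null(ch)) chol_prop <- ch
      }
    }
  }
  post_n <- iterations - burn_in
  list(chain = chain,
       acceptance = if (post_n > 0) accept_post / post_n else NA_real_)
}

# Curvature-based proposal covariance: inverse of the negated numerical
# Hessian of the log posterior at (or near) its mode.  NULL when the
# Hessian is not usably positive definite.
curvature_cov <- function(log_post, at) {
  H <- tryCatch(stats::optimHess(at, log_post), error = function(e) NULL)
  if (is.null(H) || any(!is.finite(H))) return(NULL)
  S <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(S) || any(!is.finite(S)) || any(diag(S) <= 0)) return(NULL)
  (S + t(S)) / 2
}
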