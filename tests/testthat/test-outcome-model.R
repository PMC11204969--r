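test_that("the weighted Weibull log-likelihood matches closed forms", {
  X <- matrix(0, 1, 1, dimnames = list(NULL, "x"))
  p <- list(shape = 1, log_lambda = 0, beta = c(x = 0))
  # t = 1, event, k = 1, lambda = 1: log h(1) = 0, H(1) = 1
  expect_equal(weighted_weibull_loglik(p, 1, 1, X), -1)
  expect_equal(weighted_weibull_loglik(list(shape = -1, log_lambda = 0,
                                            beta = c(x = 0)), 1, 1, X),
               -Inf)
})

test_that("doubling a weight equals duplicating the subject", {
  set.seed(22)
  n <- 12
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  t <- rexp(n); ev <- rbinom(n, 1, 0.6)
  p <- list(shape = 1.3, log_lambda = -0.5, beta = c(a = 0.4, b = -0.2))
  w <- rep(1, n); w[3] <- 2
  dup <- c(seq_len(n), 3)
  expect_equal(
    weighted_weibull_loglik(p, t, ev, X, w),
    weighted_weibull_loglik(p, t[dup], ev[dup], X[dup, ], rep(1, n + 1)))
})

test_that("the likelihood agrees with a term-by-term summation oracle", {
  set.seed(23)
  n <- 20
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  t <- c(rexp(n - 3), 0, 0, 0)
  ev <- c(rbinom(n - 3, 1, 0.5), 0L, 0L, 0L)  # zero-time censored records
  w <- runif(n, 0.2, 3)
  k <- 1.4; ll0 <- -0.7; beta <- c(a = 0.3, b = -0.5, c = 0.1)
  oracle <- 0
  for (i in seq_len(n)) {
    eta <- sum(X[i, ] * beta)
    h <- ev[i] * (log(k) + ll0 + (k - 1) * log(t[i]) + eta)
    if (ev[i] == 0) h <- 0
    oracle <- oracle + w[i] * (h - exp(ll0) * t[i]^k * exp(eta))
  }
  got <- weighted_weibull_loglik(list(shape = k, log_lambda = ll0,
                                      beta = beta), t, ev, X, w)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("a degenerate treatment prior dominates the posterior", {
  co <- make_cohort(500, seed = 24)
  pr <- prior_spec(treatment_mean = 0.5, treatment_sd = 1e-6)
  d <- fit_outcome_posterior(co, prior = pr,
                             mcmc = mcmc_config(2000, 1000, 1, seed = 6))
  expect_lt(abs(mean(d[, "ablation"]) - 0.5), 0.01)
})

test_that("exponential data bring the shape posterior to one", {
  co <- make_cohort(1400, seed = 25, shape = 1)
  d <- fit_outcome_posterior(co, mcmc = mcmc_config(3000, 1500, 1, seed = 7))
  s <- summarize_posterior(d)
  sh <- s[s$parameter == "shape", ]
  expect_gt(sh$cri_high, 1)
  expect_lt(sh$cri_low, 1.1)
})

test_that("pooling concatenates draws without reweighting", {
  a <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("shape", "ablation")))
  b <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("shape", "ablation")))
  pooled <- pool_posteriors(list(a, b))
  expect_equal(nrow(pooled), 10L)
  expect_equal(attr(pooled, "set"), rep(1:2, each = 5))
  # pooling a set with itself doubles counts, quantiles unchanged
  twice <- pool_posteriors(list(a, a))
  expect_equal(nrow(twice), 10L)
  expect_equal(quantile(twice[, "ablation"], c(0.25, 0.5, 0.75)),
               quantile(a[, "ablation"], c(0.25, 0.5, 0.75)))
  colnames(b) <- c("shape", "other")
  expect_error(pool_posteriors(list(a, b)), "mismatched")
  # full-protocol arithmetic: 500 sets x 10,000 draws pool to 5,000,000
  expect_equal(500 * 10000, 5e6)
})

test_that("posterior summaries transform to the hazard-ratio scale", {
  d <- matrix(rep(0.3, 10), ncol = 1, dimnames = list(NULL, "ablation"))
  s <- summarize_posterior(d)
  expect_equal(s$median, 0.3)
  expect_equal(s$cri_low, 0.3)
  expect_equal(s$cri_high, 0.3)
  expect_equal(s$hr, exp(0.3))
  expect_error(summarize_posterior(matrix(numeric(0), 0, 1)), "empty")
})

test_that("the Gelman-Rubin statistic follows its closed form", {
  set.seed(26)
  ch <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  r <- gelman_rubin(list(ch, ch, ch))
  n <- nrow(ch)
  expect_equal(r$psrf, rep(sqrt((n - 1) / n), 2))
  # two chains around separated means: direct-formula oracle
  c1 <- rnorm(50, 0, 1); c2 <- rnorm(50, 5, 1)
  r2 <- gelman_rubin(list(c1, c2))
  W <- mean(c(var(c1), var(c2)))
  B_n <- var(c(mean(c1), mean(c2)))
  expect_equal(r2$psrf, sqrt((49 / 50 * W + B_n) / W))
  expect_gt(r2$psrf, 1.1)
  expect_error(gelman_rubin(list(c1)), "two chains")
  expect_error(gelman_rubin(list(c1, c2[1:10])), "unequal")
})

test_that("an all-censored cohort warns and returns a prior-dominated fit", {
  co <- make_cohort(300, seed = 27)
  co$event <- 0L
  expect_warning(
    d <- fit_outcome_posterior(co, prior = prior_spec(treatment_mean = 0,
                                                      treatment_sd = 0.2),
                               mcmc = mcmc_config(1500, 700, 1, seed = 8)),
    "censored")
  expect_lt(abs(mean(d[, "ablation"])), 0.25)
})

test_that("pooling across pseudo-populations widens the interval", {
  widths <- replicate(2, NA)
  for (r in 1:2) {
    co <- make_cohort(700, seed = 30 + r)
    ps <- fit_ps_posterior(co, mcmc = mcmc_config(3000, 1500, 150,
                                                  seed = 40 + r))
    m <- mcmc_config(1500, 700, 1)
    sets <- lapply(seq_len(nrow(ps$scores)), function(d) {
      compute_stabilized_weights(ps$scores[d, ], co$ablation)
    })
    draws <- lapply(seq_along(sets), function(s) {
      mm <- m; mm$seed <- 100 * r + s
      fit_outcome_posterior(co, sets[[s]], mcmc = mm)
    })
    pooled <- pool_posteriors(draws)[, "ablation"]
    # single pseudo-population at the posterior-mean propensity score
    w_mean <- compute_stabilized_weights(colMeans(ps$scores), co$ablation)
    mm <- m; mm$seed <- 999 + r
    single <- fit_outcome_posterior(co, w_mean, mcmc = mm)[, "ablation"]
    wid <- function(x) diff(quantile(x, c(0.025, 0.975), names = FALSE))
    widths[r] <- wid(pooled) / wid(single)
  }
  # uncertainty propagation: pooled interval at least as wide on average
  # (small Monte-Carlo slack for the reduced-scale chains)
  expect_gt(mean(widths), 0.97)
})
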