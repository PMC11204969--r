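# bayestte

Bayesian target trial emulation for comparative survival analysis of two
treatment strategies in registry-style observational data.

## The problem

Partial hepatectomy and ablation are the two standard curative-intent
procedures for localized early-stage hepatocellular carcinoma (HCC) in
elderly patients, and their relative effect on overall survival is
contested. Randomized comparisons are lacking; registry/claims data exist
but treatment choice is confounded by tumor size, liver disease and
comorbidity. `bayestte` implements a fully Bayesian emulation of the
hypothetical head-to-head trial:

1. **Trial emulation** — eligibility rules (age 66–100 at diagnosis,
   diagnosis inside the accrual window, stage I–II, tumor ≤ 5 cm — or
   ≤ 3 cm for the subgroup — first qualifying surgery within one year of
   diagnosis, continuous enrollment), intention-to-treat arms from the
   first procedure received, time zero at surgery, censoring at crossover
   to the other procedure type or at the administrative study end.
2. **Prior elicitation** — published hazard ratios HR₁…HR_m are reduced to
   their median and raw median absolute deviation; the treatment log
   hazard ratio gets the prior
   β_A ~ N(log median, (c · MAD/median)²), with inflation factor c
   (default 3) and a floor on the scale so the prior stays proper and
   weakly informative.
3. **Bayesian propensity scores** — logistic regression
   A_i ~ Bernoulli(logit⁻¹(xᵢᵀγ)) with diffuse N(0, 100) priors, sampled
   by adaptive random-walk Metropolis; the chain (10,000 iterations,
   5,000 burn-in, thinned by 10) yields 500 retained propensity-score
   draws.
4. **Multiple pseudo-populations** — each retained draw becomes a
   stabilized inverse-probability-of-treatment weight vector
   swᵢ = P̂(A = aᵢ) / P(A = aᵢ | xᵢ), truncated at its upper 99.5th
   percentile. Keeping the 500 weight sets separate propagates
   propensity-score uncertainty instead of collapsing it.
5. **Weighted Bayesian Weibull outcome model** — hazard
   h(t | x) = k λ t^{k−1} exp(xᵀβ + A β_A) (the Weibull family makes this
   identical to the accelerated-failure-time form), weighted
   log-likelihood, priors β_A from step 2, N(0, 10²) on covariates and
   the log baseline rate, Exp(1) on the shape k. Per-pseudo-population
   posteriors are pooled by concatenation (500 × 10,000 draws at full
   protocol scale) and summarized as posterior medians with equal-tailed
   95% credible intervals, reported on both the log-HR and HR scale.
6. **Diagnostics and reporting** — Gelman–Rubin PSRF over five
   independent chains, standardized-mean-difference balance tables,
   Kaplan–Meier curves, log-rank test, a Table-1-style descriptive
   summary, and a single-weight frequentist IPTW Weibull comparator.

Because the motivating registry (SEER-Medicare) is restricted, the package
ships a seeded synthetic-registry generator with the same statistical
anatomy — confounded treatment assignment, Weibull survival,
administrative censoring, and deliberately rule-violating records — so the
entire pipeline is testable end to end.

## Worked example

```r
library(bayestte)

cfg <- pipeline_config(
  registry_config = registry_config(n = 1300, seed = 1),
  ps_mcmc       = mcmc_config(10000, 5000, 100),  # 50 retained score sets
  outcome_mcmc  = mcmc_config(4000, 2000, 1),
  n_weight_sets = 50L, diagnostic_chains = 5L, seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
== Bayesian target trial emulation report ==
Cohort: 1170 subjects (ablation 814, hepatectomy 356)
Treatment prior: normal(0.489, sd 0.914) on the log HR
Eligibility screening: 1300 in, 1170 included, 130 excluded
                   rule n_excluded
 missing_diagnosis_date         16
                    age         34
                  stage         16
             tumor_size         16
             enrollment         16
   no_surgery_in_window         16
    same_day_procedures         16
Ablation vs hepatectomy: log HR 0.16 (95% CrI 0.00, 0.32); HR 1.17 (1.00, 1.38)
Unweighted log-rank: chi-square 8.26, p = 0.00406
Kaplan-Meier estimate:
  ablation: n = 814, events = 558, median survival = 3.7 years
  hepatectomy: n = 356, events = 223, median survival = 4.6 years
Max propensity-model PSRF: 1.0153
Max outcome-model PSRF: 1.0403
```

Reading the output: 130 of 1300 synthetic records violate an eligibility
rule and are attributed to their first failing rule in flowchart order.
The elicited prior is centered at log(1.631) ≈ 0.489. For this synthetic
draw the pooled posterior gives a hazard ratio of 1.17 (95% CrI 1.00–1.38)
for ablation versus hepatectomy — the generator's true conditional log HR
is 0.30, which the interval covers. The unweighted Kaplan–Meier gap
(3.7 vs 4.6 years median survival) is wider than the adjusted effect, as
expected when sicker patients preferentially receive ablation.
`report$balance` shows every covariate's absolute standardized mean
difference pulled below 0.07 after weighting (tumor size starts at 0.46).

The synthetic evidence table
`inst/extdata/literature_hr_synthetic.csv` (a constructed stand-in, not
extracted from any publication) can be passed via
`pipeline_config(evidence = ...)`; its median (1.631) and MAD (0.497)
reproduce the default prior inputs.

A thin command-line wrapper is provided:

```sh
Rscript inst/scripts/run_pipeline.R --n 1146 --seed 1 --out results/
```

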