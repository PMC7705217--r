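# ropebest

Robust Bayesian estimation of pre/post change in questionnaire data, with
ROPE decisions — for clinical-psychology and epidemiology researchers who
need to quantify how symptom severity, psychosocial stress or behavior
changed between two assessments across many diagnostic groups, including
very small ones.

## The model

Each participant contributes a difference score `d_i = T1_i − T0_i` (current
minus retrospective baseline assessment). Change scores are modelled with
t-distributed noise so outliers widen the tails instead of inflating the
scale:

```
d_i ~ t(ν, μ_g(i), σ_g(i))
ν   ~ Exponential(λ = 1/30)            (optionally truncated at a floor)
μ_g = β0 + β_g,  Σ β_g = 0             (multi-group, ANOVA-like)
σ_g ~ Gamma(mode ω, sd s),  ω, s ~ broad uniforms
```

Single-group and two-group (Bayesian t-test analog) variants and a robust
linear regression share the same noise family. Posteriors are summarized by
medians and 95% highest-density intervals (HDI), and standardized effect
sizes

```
δ = μ / σ                               (one group)
δ = (μ₂ − μ₁) / sqrt((σ₁² + σ₂²) / 2)   (two groups / contrasts)
```

are tested against a region of practical equivalence (ROPE), by default
−0.2 < δ < 0.2: the null is accepted when the HDI of δ lies completely
inside the ROPE, the alternative when it lies completely outside, and
anything else is inconclusive. Reports also carry the posterior mass above
zero and below / in / above the ROPE.

Around the estimation core the package provides questionnaire scoring and
reliability (Cronbach's α, KR-20), descriptive tables with explicit
denominators, an inclusion-filter ledger, MCMC diagnostics (effective
sample size, split-chain Gelman–Rubin) with an automatic ν-floor
remediation ladder for fits that overcompensate outliers, a seeded
synthetic cohort generator with known ground truth, and a config-driven
pipeline. Sampling runs on JAGS via rjags.

## Worked example

Simulate a two-group cohort in which the depression group's stress score
truly increases (μ = 1.55 raw points, σ = 3.1, so δ = 0.5) while controls
barely move, then fit the robust multi-group model and render the report:

```r
library(ropebest)

cfg <- cohort_config(
  group_sizes = c(DP = 200, HC = 300),
  true_change = data.frame(group = c("DP", "HC"), variable = "stress",
                           mu = c(1.55, 0.2), sigma = c(3.1, 2.7), nu = 30),
  seed = 11)
cohort <- generate_cohort(cfg)
diffs  <- difference_scores(cohort, "stress")
fit    <- fit_multi_group(diffs, cohort$group,
                          model_spec("multi_group", chains = 2,
                                     draws_per_chain = 2000, seed = 11))
render_reports(summarize_multi_group(fit))
#>                  row    mu sigma mu_hdi_ll mu_hdi_ul delta delta_hdi_ll
#> 1                 DP  1.57  2.93      1.12      1.96  0.54         0.38
#> 2                 HC -0.09  2.80     -0.41      0.23 -0.03        -0.15
#> 3 Contrast MD vs. HC  1.65    NA      1.14      2.17  0.58         0.39
#>   delta_hdi_ul pct_delta_gt_0 pct_below_rope pct_in_rope pct_above_rope
#> 1         0.68         100.00            0.0         0.0            100
#> 2         0.08          29.03            0.1        99.9              0
#> 3         0.76         100.00            0.0         0.0            100
#>              verdict
#> 1 accept_alternative
#> 2        accept_null
#> 3 accept_alternative
```

The DP row recovers the simulated effect: a median change of 1.57 raw
points (truth 1.55), δ = 0.54 with 95% HDI [0.38, 0.68] entirely above the
ROPE, hence `accept_alternative`; the control row's HDI sits inside the
ROPE and accepts the null. The contrast row pools the disorder groups
(here just DP) against HC. A single decision reads the same way:

```r
rope_decision(effect_size_single(fit$draws$mu_DP, fit$draws$sigma_DP))
#> accept_alternative: 95% HDI [0.380, 0.683] vs ROPE [-0.20, 0.20]
#>   % > 0: 100.00 | < ROPE: 0.00 | in ROPE: 0.00 | > ROPE: 100.00
```

`run_pipeline(run_config(...))` chains all stages (simulation or CSV input,
descriptives, fits with the remediation ladder, reports, regression,
diagnostics sidecars, manifest) into one seeded, reproducible run, and
`inst/cli/ropebest.R` exposes `simulate` and `run` subcommands for shell
use.

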