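---
title: "Robust Bayesian change analysis with ROPE decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Bayesian change analysis with ROPE decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surveys that ask participants to rate their symptoms, stress and behavior
both for the current moment (T1) and retrospectively for a pre-event
baseline (T0) yield per-participant difference scores `d = T1 − T0` across
many diagnostic groups of very different sizes — from several hundred
participants down to a handful. Two features make naive normal-theory
analysis fragile here: bounded sum scores produce outlying change values,
and tiny groups make variance estimates unstable. This package implements
a robust Bayesian estimation pipeline for exactly this setting, from
questionnaire scoring through MCMC, decision rules and report tables.

## Model and priors

All models describe the noise with a location-scale t distribution. The
normality parameter ν is estimated from the data under an exponential
prior with rate 1/30 (prior mean 30): when the data are close to normal
the posterior of ν drifts high and the model behaves like a normal model;
when outliers are present ν drops and the tails absorb them without
inflating σ.

* **Single group**: `d_i ~ t(ν, μ, σ)`, μ normal, σ uniform.
* **Two groups** (Bayesian t-test analog): group-specific μ and σ, shared ν.
* **Multi-group (ANOVA-like)**: `d_i ~ t(ν, β0 + β_g, σ_g)` with normal
  priors on the grand mean and deflections, and a gamma prior on the
  group scales σ_g whose mode and sd get broad uniform hyperpriors, so
  group spreads are partially pooled — this is what lets a six-person
  group borrow strength for its scale without forcing equal variances.
* **Regression**: same t noise, normal priors on standardized
  coefficients.

Deflections are identified by sum-to-zero recentering applied to every
retained draw. Cell means `μ_g = β0 + β_g` are invariant to that choice,
which is why the reports are built from cell means, not deflections. The
two-group model shares a single ν across groups, matching the t-test-analog
family; per-group ν is out of scope.

### Prior constants

The named prior families need constants; the package uses non-committal,
data-scaled defaults: the location prior is centered at the sample mean
with scale 100 × the sample sd; the single-group σ prior is uniform on
(sd/1000, sd × 1000); the gamma hyperpriors for group scales are uniform on
the same range; deflections get a normal prior with scale 10 × the pooled
sd; regression coefficients get scale 10 on the standardized scale. On any
data set whose scores are not astronomically scaled these priors are flat
over the plausible region, and the conjugate-limit test in the suite
verifies that with ν forced high and σ pinned, the μ posterior matches the
closed-form normal answer. All constants are overridable via
`model_spec()`.

The exponential ν prior is placed on ν itself, so its support starts at 0.
A `nu_floor` truncates it from below; the canonical shifted
parameterization (1 + exponential) is available by setting the floor to 1
but is not the default.

## Effect sizes, HDI and the ROPE decision

Inference is summarized on the effect-size scale: `δ = μ/σ` per draw for
one group, and `δ = (μ₂ − μ₁)/√((σ₁² + σ₂²)/2)` for two. δ is summarized
as the **median of per-draw ratios**, not the ratio of medians: per-draw
propagation keeps σ's uncertainty inside the δ posterior. On point-mass
inputs both conventions coincide, which is what the printed-triple
consistency checks in the test suite exercise.

The 95% highest-density interval is computed as the narrowest contiguous
window over the sorted draws containing ⌈0.95·N⌉ points; ties break toward
the lower window so results are deterministic. The ROPE (default
−0.2 < δ < 0.2, wider than half a small effect to avoid false alarms on
negligible effects) is applied on the δ scale only — practical equivalence
is hard to define in raw scores for novel situations. The decision is
three-way: HDI completely inside the **closed** ROPE accepts the null, HDI
completely outside accepts the alternative, any overlap is inconclusive.
Closed-interval containment means an HDI endpoint that exactly touches a
ROPE bound still accepts the null; this boundary reading matters in
practice for contrast rows whose lower HDI limit lands on −0.2. Alongside
the verdict the reports carry the posterior mass above zero and below / in
/ above the ROPE, so trends remain visible when the verdict is
inconclusive.

The pooled contrast row compares the mental-disorder groups against the
controls: per draw, `μ_MD` is the unweighted mean of the disorder groups'
cell means (a by-n weighted option exists; the two agree on balanced
designs) and `σ_MD` is the root mean of their variances. Unweighted
pooling is the default so that one very large group does not dominate the
contrast's meaning; it is an open modelling choice and is exposed as a
parameter.

## Convergence and remediation

Effective sample size is computed as `N / (1 + 2 Σ ρ_k)` with
autocorrelations averaged across chains and truncated by the
initial-positive-sequence rule; the split-chain Gelman–Rubin statistic and
a per-chain density-overlap score mechanize the usual trace/density
inspections (the overlap is reported, not gating). The gate requires ESS ≥
10,000 and PSRF ≤ 1.05 on the parameters of interest — cell means and
group scales; ν is deliberately not gated, because its slow mixing is
expected and does not impeach the location/scale estimates.

Fits of heavy-tailed count-like variables can fail in a characteristic
way: the ν posterior piles up near zero and μ and σ collapse with it
(outlier overcompensation). The diagnostics flag this signature, and the
remediation ladder refits with the ν prior truncated at 1, then at 2; a
fit still failing after the last rung is a hard, structured error carrying
the report. The gate is idempotent on passing fits.

Default run size is 4 chains × 12,500 retained draws (500 adaptation +
500 burn-in): group scales are the slowest-mixing gated parameters (ESS
per draw around 0.2–0.35 at a 2,233-participant cohort), and this is the
smallest round size that attains the ESS target on them without
remediation. Reproducibility is exact: every chain gets a
Mersenne-Twister stream seeded deterministically from the spec seed, so
the same data, spec and seed give identical draws.

## The synthetic cohort generator

Because raw survey data of this kind are typically not public, the
generator is a first-class module that produces cohorts with the
statistical structure the analysis assumes: eleven diagnostic groups with
configurable sizes (defaults are the study's sizes, n = 2,233 total),
bounded integer sum scores at two time points, individual change drawn
from a location-scale t with per-group (μ, σ, ν) truth, and covariates
(age from a truncated normal with mean 33.2 and sd 12.7, female and
relationship indicators as Bernoulli draws at the sample marginals). T0
comes from a truncated normal on the score range — inference consumes only
differences, so baseline shape is low-stakes; location 8 and spread 4 on
the default 0–20 stress range were chosen once as a plausible mid-scale
baseline. Scores are clamped to the range and rounded to the integer grid,
since questionnaire sums are integers; a flag disables both because
clamping biases effect-size recovery near range edges, which matters for
calibration studies. One master seed expands into per-group, per-variable
substreams, so adding a variable never perturbs existing draws.

What the generator does **not** emulate: item-level response processes
(no IRT), missing data, recall bias in the retrospective baseline, and any
dependence of covariates on change. Passing recovery tests therefore shows
that the estimation machinery is calibrated for t-noise difference scores,
not that real retrospective surveys are free of those complications.

The default per-group change truths for the stress variable use locations
around 0.8–1.6 raw points with spreads near 2.4–3.1 and ν = 30 —
magnitudes typical of a 10-item 0–2 stress sum in a stressed population.
The calibration study in the test suite instead assigns a standardized
change of exactly 0.5 to six groups and 0 to the rest (σ = 1, ν = 30,
clamping off) and checks, over ten seeded replicates at the study's group
sizes, that cell means are recovered within ±0.15 (averaged over
replicates, for groups with n ≥ 30 — below that, single-cohort sampling
noise alone exceeds the bound) and that the alternative is accepted in at
least 90% of replicates for the δ = 0.5 groups with n ≥ 80, with no false
alarms in the null groups.

## Scoring and reliability

Scales are declared as metadata (item count, response range, dichotomous
flag, subscales as 1-based index lists, optional reverse-keyed items); the
default registry ships the shapes of the instruments in this survey
family. Scoring is a validated sum: out-of-range or missing entries are
rejected with respondent/item coordinates — no imputation or prorating,
since none is defensible without a stated missingness model. No default
scale applies reverse scoring; the worry scale's published form has
reverse-keyed items, but the registry follows the administered scoring and
the flag is available per item.

Cronbach's α uses the variance formula with the sample (n−1) convention
throughout; KR-20 is computed from item proportions with the same
convention, which makes it *exactly* α's dichotomous special case — the
suite asserts agreement to 1e-12. One caveat worth recording: the folk
rule "duplicating an item never lowers α" holds for internally consistent
batteries (positively correlated items) but is false for arbitrary
matrices — with uncorrelated integer items a duplicate can lower α
substantially. The property test simulates a common factor accordingly.

Frequency tables take the denominator as an explicit argument and round
percentages half-up to 2 decimals (base R's round-half-even produces
off-by-one last digits on published values). Reports in this survey family
switch denominators silently between the full sample and subsamples;
making the denominator explicit is the guard rail. One known source
inconsistency is handled by following the table rather than the text: a
prose statement of "approximately 63%" for increased need of therapeutic
support corresponds to the table's No = 63.20% / Yes = 36.80% split read
the other way around.

## Numerical choices and degenerate inputs

* Zero-variance data are rejected before sampling, naming the variable.
* Groups with fewer than 2 observations are rejected by name; n = 6 groups
  fit fine thanks to the pooled scale prior.
* Rank-deficient regression designs are rejected naming the collinear
  columns; predictors are standardized internally and draws
  back-transformed, so prior scales are interpretable regardless of units.
* HDI ties break toward the lowest window; `mass = 1` returns [min, max].
* Percentages are computed on unrounded masses; only emitted tables are
  rounded (half-up, 2 decimals).
* The intercept-only regression reduces exactly to the single-group model
  (same code path), which the suite checks.

## Limitations

Retrospective baselines mean the model quantifies perceived change, with
whatever recall bias the data carry. Per-variable analyses are fit
independently with no multiplicity adjustment — deliberately, matching the
exploratory reporting style this pipeline reproduces, and worth remembering
when many variables are scanned. Bayes factors, variational approximations
and multivariate outcome models are out of scope.
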