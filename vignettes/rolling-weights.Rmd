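---
title: "Rolling weights: estimating age-varying polygenic score effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rolling weights: estimating age-varying polygenic score effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollscore)
```

## The problem

A polygenic score (PGS) summarizes a person's genetic liability for a trait
as a single standardized predictor. When the trait is measured repeatedly
across a wide age span in family cohorts, the natural question is whether the
genetic effect is constant over the life course or changes with age.
Stratifying by age is fragile: sample sizes differ wildly between ages, and
apparent age differences in the PGS effect can simply reflect who happened to
be measured when.

`rollscore` implements a varying-coefficient approach built from three parts:

1. a **rolling age-weight kernel** that, for each integer *focus age*, gives
   weight 1 to observations at that age and smoothly down-weights
   observations at neighbouring ages;
2. a **weighted linear mixed model** with a family random effect, fitted once
   per focus age, whose PGS coefficient is the age-specific effect estimate;
3. a **family-block bootstrap** that produces standard errors and 95%
   confidence intervals robust to the within-family and within-person
   dependence.

Upstream of the model, ordinal questionnaire items can be converted to a
latent trait score per wave with a Generalized Partial Credit Model (GPCM),
so that scores are relative to the other participants of the same
data-collection wave and occasion ("wave") effects are filtered out.

## The weight kernel

For focus age $c$ and observation ages $x$, weights are built in three steps:

$$w_1 = 1 - |c - x|^{s}, \qquad
  w_2 = \frac{w_1 - \min(w_1)}{\max(w_1) - \min(w_1)}, \qquad
  w = w_2^{\,d}.$$

* **center** $c$ — the focus age, iterated over integer years.
* **shoulder** $s > 0$ (default 1.5) — curvature of the raw kernel near its
  peak; larger values flatten the peak.
* **decay** $d > 0$ (default 25) — exponent applied to the min–max-scaled
  weights; larger values narrow the effective age window. With the default
  configuration on ages 12–70 the window where weights exceed 0.01 is
  roughly $\pm 10$ years.

Properties worth knowing:

* the observation(s) nearest the center get weight exactly 1 and the
  observation most distant gets exactly 0 — both are consequences of the
  min–max step, not of the raw kernel;
* weights are **data-relative**: the same parameters give different absolute
  weights on cohorts with different age spans, because the min–max step
  rescales by the observed extremes. Duplicating rows changes nothing;
* a wider distribution of weights (smaller decay) smooths the estimate
  sequence across focus ages; a narrower one is more sensitive to local
  fluctuation. Both behaviours are covered by tests.

One notational ambiguity deserves a flag: the source formula for step 3 can
be read as exponent $e^{k}$ with $k = 25$, which would be $\approx 7\times
10^{10}$ and would annihilate every off-center weight. That reading
contradicts the method's stated purpose and its published illustration, so
here the decay parameter *is* the exponent, with default 25.

A dataset in which every observation shares one age makes the min–max step
undefined (0/0); `compute_weights()` then assigns uniform weight 1 with a
warning, which reduces the weighted fit to the pooled fit.

## The per-age model

At each focus age the model for measure $m$ of individual $i$ in family $f$ is

$$Y_{mif} = \beta_{0f} + \mathbf{x}_{mi}'\boldsymbol\beta + \varepsilon_{if},$$

with fixed effects for the PGS, age, age², sex, genotyping-array dummies and
five ancestry principal components, and a family random intercept (optionally
also a family random slope on age). Age covariates stay in every per-age
model because a range of ages is present in each weighted fit.

Weights enter as **residual precision**: the marginal covariance of a family
block is $V_f = Z_f G Z_f' + \sigma^2 W_f^{-1}$, the standard weighted-LMM
convention. The source describes only the fixed-effect weighted
least-squares formula $\hat\beta = (X'WX)^{-1}X'WY$ and is silent on how
weights meet the random effects; residual-precision weighting reproduces
exactly that formula when the variance components are zero and is what the
mixed-model software named by the source does with observation weights.

Estimation profiles both $\boldsymbol\beta$ and $\sigma^2$ out of the
(restricted) likelihood analytically, leaving a 1- or 2-dimensional
optimization over the variance-component ratios $\gamma = G/\sigma^2$,
solved with bounded search from $\gamma = 0$ (boundary fits are returned
with a flag, not an error). Family blocks never materialize as dense
matrices — the Woodbury identity reduces every likelihood evaluation to
per-family aggregates, so a 30,000-row fit takes well under a second.
Standard errors come from the GLS information matrix
$\sigma^2 (X'V^{-1}X)^{-1}$.

Numerical choices:

* rows with final weight $< 10^{-8}$ are dropped from each per-age fit for
  stability; the **effective N** (the sum of *all* weights, the weighted
  analogue of sample size) is recorded before dropping;
* REML is the default criterion; ML is available and is what the
  log-likelihood nesting test uses;
* a single family is allowed (the family intercept is then confounded with
  the fixed intercept but the fit is well defined) — this keeps the
  family bootstrap total and well defined on degenerate resamples;
* exact collinearity among array dummies is resolved by dropping the
  aliased dummy with a warning; collinearity involving any other column is
  an error naming the columns.

**Pseudo-R²** for the PGS is the proportional reduction in total model
variance (family components + residual) between the covariate-only fit and
the fit with the PGS, on identical rows and weights. For a standardized
outcome and PGS with marginal effect $\beta$ this is $\approx \beta^2$,
which is the consistency check the tests apply.

## Rolling driver and bootstrap

`run_rolling()` standardizes nothing itself — `standardize_measures()` is an
explicit, once-per-dataset step that z-scores the phenotype, PGS and PCs and
creates the standardized-age column and its square (the square of the
z-score, not the z-score of the square). The kernel always operates on
**raw** ages; the model's age covariates use standardized age. Focus ages
iterate over every integer in the configured range, including ages with zero
raw observations — neighbouring ages carry the information, which is the
point of the method.

For each focus age, `bootstrap_ci()` draws resamples of **complete
families** with replacement (as many families as observed; each draw is a
distinct cluster), recomputes the kernel weights on the resample's age
vector, refits, and uses the SD of the resampled PGS coefficients as the
bootstrap SE. The 95% CI is the normal approximation
$\hat\beta \pm 1.96 \cdot \mathrm{SE}_{boot}$ (a percentile option exists);
an age is flagged significant when its CI excludes zero. Model-implied SEs
are also reported, but the CI always comes from the bootstrap, which the
source motivates by model SEs being slightly underestimated. Replicates
whose refit fails (e.g. a rank-deficient resample) are dropped and counted;
more than 20% failures at one age is an error.

Reproducibility contract: every replicate's RNG stream is derived
deterministically from `(seed, focus age, replicate index)`, so results are
bit-identical across runs and independent of execution order — per-age
analyses and replicates could be executed concurrently without changing any
output.

## The GPCM phenotyping stage

Items with $K$ ordered categories follow
$P(X_{ij} = k \mid \theta_i) \propto \exp\sum_{v \le k} a_j(\theta_i - b_{jv})$,
with discrimination $a_j$ and step parameters $b_{jv}$. Estimation is
marginal maximum likelihood by EM over a standard-normal latent prior on a
fixed grid of 61 equally spaced nodes on $[-6, 6]$ (tolerance $10^{-6}$ on
the log-likelihood change, cap 500 iterations, error with the trace if hit).
The M-step re-optimizes each item from its current parameters, so the
marginal log-likelihood is non-decreasing up to float accumulation. The
scale is identified by the prior; if the first item's slope comes out
negative the whole solution is flipped ($a \to -a$, $b \to -b$), an exact
symmetry of the model.

Scoring is **EAP** (posterior mean, with posterior SD reported). Persons
with up to `max_missing` (default 2) missing items are retained and scored
on their observed items; missing entries simply contribute nothing to the
likelihood — no imputation step is used anywhere, also where the original
analyses imputed before scoring. Because each wave is fitted and scored
separately, scores are relative to the wave and occasion effects are
filtered; per-wave means are near zero but not exactly zero (EAP shrinkage
is nonlinear), which is harmless because the analysis pipeline standardizes
the phenotype downstream.

## What the generator emulates — and what it does not

`simulate_measures()` produces the stated world the tests run in: families
of 1–4 members (so ~2.3 persons per family), 1–3 measures per person
(~1.8 on average), ages uniform on 12–70 by default with a bimodal
adolescent/adult preset available, a sibling-like within-family PGS
correlation of 0.5 (shared + individual component, marginal variance 1), a
constant standardized genetic effect $\beta = 0.05$ (matching the pooled
effect size scale reported for this design), a family intercept variance of
0.3 against a residual variance of 0.65 (an intraclass correlation around
0.3, typical for behavioural traits in family data), a small sex effect of
−0.1, and three genotyping-array labels with null effects. Item data are
drawn from the GPCM with discriminations in [0.8, 2] and sorted steps in
[−2, 2] (3 categories by default, 5 for Likert-like instruments), with 5%
completely-at-random missingness.

The generator deliberately omits: genotype-level structure (the PGS is
simulated directly, not built from SNPs), assortative mating and
parent–offspring structure (families are exchangeable members), age-varying
residual variance, selective participation, and real measurement
non-invariance across waves (wave shifts are simulated only as step-parameter
offsets). A green test therefore establishes that the estimator recovers the
effects *its own model family generates* — parameter recovery,
calibration, and qualitative shape recovery — not that the published
cohort estimates are reproduced; those depend on restricted registry data
that is available only on request.

## Acceptance-scale checks

The acceptance suite (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) verifies, at desk scale: the kernel identity
(weight exactly 1 at the focus age); the analysis counts over the two focus
age grids (59 analyses over ages 12–70, 58 over 16–73); agreement of the
weighted GLS fixed effects with an independent dense-matrix oracle to
$10^{-6}$; recovery of a constant $\beta = 0.05$ at ~30k measures with
pseudo-R² $\approx \beta^2$; a step-shaped $\beta(\text{age})$ (0.05 up to
age 41, 0 after) producing higher early-age than late-age estimate means in
$\ge 95\%$ of 50 replicates; null calibration of the bootstrap CI (3–9%
exclusion of zero across 200 null datasets); and the GPCM round trip
(score–truth correlation > 0.9; wave means within ±0.05). Bootstrap
replicates are reduced (10 per age) where only counts are at stake;
the calibration check uses the full 100.

## Known limitations

* No kinship-matrix (GRM) random effects — family-ID grouping only; no
  non-Gaussian outcomes.
* The random family age-slope variant assumes slope and intercept are
  uncorrelated (diagonal G).
* The kernel family is fixed (shoulder/decay); no Gaussian or tricube
  alternatives.
* Wald p-values are reported for the pooled fit only; per-age inference
  should rely on the bootstrap CIs.
* EAP wave means are approximately, not exactly, zero; downstream
  standardization subsumes this.
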