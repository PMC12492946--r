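---
title: "Reaction-norm analysis of feed-intake resilience: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm analysis of feed-intake resilience: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnresilience)
```

This vignette is the package's account of the science it implements: the
models, the assumptions behind them, the tunable parameters, and the design
choices made where the methodology left room.

## The problem

Resilient pigs keep a stable daily feed intake (DFI) when the environment
turns against them; sensitive pigs swing. Because the perturbations
themselves (heat episodes, subclinical disease, management events) are
rarely recorded on farm, the first task is to *infer* from the data how
challenging each day was; the second is to estimate how much of the
response to that challenge is genetic, and whether selecting for a flat
response would drag production traits along with it.

## Stage 1 — the environmental descriptor

For every batch × day with at least `min_animals` records, the coefficient
of variation of DFI across the animals of the batch is computed (sample SD,
n−1 denominator, divided by the day mean) and log-transformed. Working
within batch removes the age/weight trend across batches; the log scale
stabilises the strictly positive, right-skewed CV.

Across all batch-days the log CV is modelled as a two-component Gaussian
mixture fitted by EM: calm days populate the low-CV component, challenge
days the high-CV component. The per-day posterior probability *p* of the
higher-mean component is the environmental descriptor used downstream as a
continuous covariate on [0, 1]. Component order is fixed by ascending means,
so "component 2 = high CV" deterministically.

Choices made here:

* `min_animals = 5` — a CV from fewer than five animals is too unstable to
  classify a day.
* EM restarts: the first start splits the data at the median; the other
  `n_starts − 1` split at random quantiles with perturbed means, and the
  best log-likelihood wins. A floor of 10⁻⁴ on component SDs discards
  collapsing starts; the fit errors only if every start collapses.
* The presence of two components is tested by a *plain parametric-bootstrap
  likelihood-ratio test*: the statistic 2(ℓ₂ − ℓ₁) is recalibrated against
  refits on data simulated from the single-Gaussian MLE. Penalised EM-test
  variants exist, but the unpenalised bootstrap LRT is self-calibrating and
  transparent; the same EM settings are applied to the observed data and
  every bootstrap replicate, which is what makes the test exact-ish by
  construction.
* The mixture is fitted on days pooled across all batches, unweighted by
  the number of animals per day.

## Stage 2 — the bivariate reaction-norm animal model

DFI records y₁ and one single-record production trait y₂ are modelled
jointly. Each animal carries three genetic effects — intercept a₁₀ and
slope a₁₁ of DFI on the gradient *p*, plus a₂ for the other trait — with
covariance **K** ⊗ **H**, and matching permanent-environmental effects with
covariance **T** ⊗ **I**. Residuals are trait-specific and uncorrelated
(**Q** diagonal): DFI and the other trait are never recorded at the same
moment, so a residual covariance is not estimable, and cross-trait
similarity beyond genetics is carried by the permanent-environmental
covariances instead. The slope is fitted for DFI only — a reaction norm
needs repeated records along the gradient, and the other traits are
measured once per lifetime.

The covariate *p* enters *uncentered*: p = 0 is the meaningful
"unchallenged" reference, and the intercept keeps its interpretation as
genetic merit in calm conditions. Fixed effects use reference-level coding
with rank-deficient columns dropped; `weight_control` and the other
measurement covariates enter as continuous terms when numeric.

**H** is the single-step combined relationship matrix. The package builds
**A** by the tabular method with inbreeding, its sparse inverse by
Henderson's rules, **G** by VanRaden's first method with observed allele
frequencies, tuned so its mean diagonal/off-diagonal match A₂₂ and blended
G ← 0.95·G + 0.05·A₂₂ to guarantee invertibility, and
H⁻¹ = A⁻¹ + [0, 0; 0, G⁻¹ − A₂₂⁻¹] with τ = ω = 1. All of these constants
are exposed as arguments; none is sacred, they follow common single-step
practice.

### REML

The restricted likelihood is evaluated through sparse mixed-model-equation
identities,

−2ℓ_R = log|R| + log|G₀| + log|C| + y′Py + (N − p) log 2π,

where C is the full MME coefficient matrix — never through the dense
marginal covariance (the equivalence of the two routes is itself asserted
by tests on small instances, tolerance 10⁻⁶). Maximisation is by
quasi-Newton (L-BFGS-B) search over the *log-Cholesky factors* of **K** and
**T** and log residual variances: every iterate is positive definite by
construction, so no step ever has to be rescued back into the parameter
space. An average-information scheme with EM fallback would converge in
fewer iterations, but each of its iterations needs selected inverses of C;
the quasi-Newton route reuses one sparse Cholesky per likelihood
evaluation, is simpler to make robust, and reaches the same optimum — and
only the converged estimates carry scientific meaning. Convergence is
declared when the relative likelihood improvement falls below `tol`
(default 10⁻⁸) with optimizer success; log-scale diagonal parameters are
bounded a few orders of magnitude around the data scale so boundary
variances (σ² → 0) stay numerically benign and are flagged per parameter.

The plain animal model (AM) drops both slope terms (**K**, **T** collapse
to 2×2). The REML ratio test statistic χ² = (−2ℓ_AM) − (−2ℓ_RNAM) is
referred to the boundary mixture ½χ²₅ + ½χ²₇, the convention used for this
null (slope variances and slope–intercept covariances zero, parameters on
the boundary). Slightly negative statistics from finite optimizer
tolerance are clamped to zero.

### Gradient summaries

All downstream quantities are closed forms in **K**: Var(a₁)(p) is a
quadratic in p; r(a₁, a₂)(p) and r(a₁, a₁₁)(p) follow by normalisation;
p* = −cov(a₁₀, a₁₁)/σ²ₐ₁₁ is simultaneously the zero of the total–slope
correlation and the vertex of the variance parabola. p* is returned
unclipped with an `in_range` flag; the default reporting grid is 101 points
on [0, 1].

## The synthetic-data generator

The generator exists so that every stage above can be validated against a
known truth. It produces: a multi-generation pedigree (founders, random
non-selfing matings); SNP genotypes by gene dropping from Hardy–Weinberg
founders (unlinked loci, optional missingness); a challenge calendar
(i.i.d. Bernoulli challenge states per batch-day — no day-to-day dependence
is asserted by the methodology, so none is simulated); and phenotypes drawn
from exactly the model of Stage 2, with breeding values sampled from
**K** ⊗ **A** (the pedigree kernel is the exactly-known truth; **H** equals
**A** when no genotypes are supplied).

Default magnitudes are the DFI–AGE column of the built-in reference table:
σ²ₐ₁₀ = 0.036, σ²ₐ₁₁ = 0.087, cov = −0.021, σ²ₐ₂ = 34.773, the matching
**T** block, σ²ₑ₁ = 0.175, σ²ₑ₂ = 12.42, mean DFI 2.36 kg/day, mean AGE
135.1 d. Small batch (SD 0.10 kg), pen (SD 0.05 kg) and sex/batch effects
on the trait give the fixed-effect structure something to do. Default desk
scale is 20 batches × 25 animals × 50 days — orders of magnitude below a
breeding-company dataset, chosen so a full REML fit takes about a minute.

### Two residual modes

The day-level CV signature that Stage 1 estimates has to come from
somewhere. The generator supports two modes:

* `heterogeneous_residual = TRUE` (default): each day's residual variance
  is scaled so the expected between-animal variance matches the day's
  target CV, drawn from the calendar's mixture component. This realises
  the bimodal log-CV distribution — the signature the descriptor needs —
  at the cost of mild residual heteroscedasticity along *p*. The mixture
  defaults (means −1.828 and −1.128 on the log-CV scale, SDs 0.15,
  prevalence 0.3) were derived analytically so that (i) the components sit
  4.7 pooled SDs apart, (ii) implied CVs stay inside the realistic
  0.10–1.31 range, and (iii) the prevalence-weighted mean day residual
  variance equals σ²ₑ₁ = 0.175, keeping the residual variance a
  well-defined estimand.
* `heterogeneous_residual = FALSE`: homoscedastic e₁ ~ N(0, σ²ₑ₁), i.e.
  *exactly* the fitted model. This is the mode for validating the REML
  machinery (parameter recovery), because the estimator's assumptions then
  hold verbatim. Under the heterogeneous mode the two-stage analysis — an
  estimated, noisy descriptor plus residual variance that grows with *p* —
  visibly biases the genetic/permanent split of the slope block; that is a
  property of the two-stage design itself (present in any real-data
  application of it), not of this implementation, and users should read
  slope-block estimates from heterogeneous data accordingly.

Two further honest prints: simulated DFI is untruncated Gaussian, so at
default parameters ~0.06% of records are non-positive (truncation would
break model-exactness; the descriptor guards on day means, not records);
and the generator draws challenge states i.i.d., so it cannot emulate
multi-day perturbation episodes — tests passing on this generator say
nothing about autocorrelated challenges.

## What the tests do and do not show

The suite validates: closed-form arithmetic against a published-scale
reference table; the sparse REML evaluation against an independent dense
oracle (≤ 15 animals); pedigree relationships against gene dropping; the
single-step H⁻¹ against the dense conditional-distribution construction;
EM against an independent mixture implementation; parameter recovery over
5 replicates of 500 animals × 50 days from the reference truth (problem
size chosen to keep the full suite in the tens of minutes; the recovery
bands are ±2 empirical SEs of the replicate mean); REMLRT power and size
under slope variance present/absent; and descriptor recovery (mean
|p̂ − p| < 0.1 with well-separated components). None of this demonstrates
performance on real data with selection, litter structure, visit-level
noise or autocorrelated challenges — all explicitly out of the generator's
scope.

## Known limitations

* Linear reaction norms only; no quadratic terms, no heterogeneous residual
  variance *along p* in the estimator.
* σ²ₚₑ₂ and σ²ₑ₂ are separated only through the cross-trait
  permanent-environmental covariances (one record per animal for trait 2);
  with weak covariances this profile is flat and the split should not be
  over-interpreted. Every fit therefore reports `pe2_flatness`, the
  −2 log-likelihood increase when a quarter of σ²ₚₑ₂ is shifted into
  σ²ₑ₂ — values near zero flag an unidentified split.
* The REMLRT degrees-of-freedom mixture (5, 7) follows the published
  convention for this null; an argument could be made for other boundary
  mixtures, and the p-values are in any case far from the decision
  threshold in realistic fits.
* No APY or other large-scale approximations of H⁻¹; the sparse solver is
  comfortable to a few thousand animals, not hundreds of thousands.
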