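---
title: "Longitudinal twin models for DNA methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal twin models for DNA methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The model

`twinmeth` decomposes individual differences in per-CpG methylation
M-values, measured in same-sex twin pairs at two occasions roughly a
decade apart, into additive-genetic (A), dominance (D) or
shared-environment (C), and non-shared (E) sources, and estimates how
much each source carries methylation levels forward across the decade.

The unit of analysis is the twin pair. Its (up to) four measurements —
twin 1 and twin 2 at occasions 1 and 2 — are modelled as multivariate
normal. Each source has a lower-triangular 2x2 Cholesky factor over the
occasions, so its within-person covariance contribution is positive
semidefinite by construction. Cross-twin blocks apply the biometrical
sharing weights: monozygotic (MZ) co-twins share all additive and
dominance effects (weights 1 and 1), dizygotic (DZ) co-twins share them
with weights 0.5 and 0.25, shared environment crosses with weight 1 in
both zygosities, and non-shared effects never cross. D and C cannot be
estimated simultaneously from twin pairs alone, so the full models are
ADE and ACE, with AE, CE and E as nested submodels.

Slot means adjust for a time-varying age covariate centered at 74
years, sex (0 = male, 1 = female) and country (0/1). The second
country's standard deviations are scaled by free per-occasion scalars
`k1`, `k2` (country 0 is the reference); standardized variance shares
are invariant to these scalars, which is asserted numerically in the
test suite.

Estimation is full-information maximum likelihood: each pair
contributes the Gaussian log-density of exactly its observed slots.
Missing occasions are handled by marginalization, never imputation, so
pairs in which one twin was measured only once stay in the analysis.

## Derived quantities

From the fitted paths of one variant:

* absolute components at occasion 1 are the squared first-column paths,
  at occasion 2 the summed squares of the second row; standardized
  components divide by the occasion total (country-0 scale);
* broad-sense heritability is A + D under ADE and A under ACE/AE;
* the cross-time correlation of source S is
  `l11 l21 / sqrt(l11^2 (l21^2 + l22^2))`, the correlation of that
  source's latent scores across occasions. Fisher-Z transforms use
  `atanh` after capping `|r|` at `1 - 1e-6` (capped and zero-variance
  sources are flagged rather than silently propagated).

ADE is retained as best-fitting when its AIC is as good as or better
than ACE's — a tie keeps ADE, and a non-converged variant loses to a
converged one. Submodels are fitted for the nested tests (full vs E,
6 df; AE vs E, 3 df; the stability test below) but never replace the
full-model estimates in reporting, since twin designs at this scale
have little power to resolve D (or C) from A.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| age centering | 74 | years; covariate is `age - 74` per occasion |
| covariate slopes | shared | one `beta_age`, `beta_sex`, `beta_country` across occasions; `occasion_specific = TRUE` frees them per occasion (+3 parameters) |
| `k1`, `k2` | free, init 1 | country-1 SD scalars, estimated per site when both countries are present |
| filter bounds | 6.25 / 1.5 | implied M-value mean outside [-6.25, 6.25] or implied SD above 1.5, at either occasion under either full model, drops the probe (strict inequalities) |
| significance thresholds | 1e-7, 1e-2 | on the 6-df full-vs-E p-value |
| stability threshold | 0.01 | low-stability rule: stability p above it |
| E-dominance threshold | 0.99 | standardized E above it at both occasions |

The mean model uses shared covariate slopes by default for parsimony
and identifiability at ~100 pairs; occasion-specific slopes are a
switch because nothing in the design forbids them — at these sample
sizes the shared-slope model is the sensible default and the likelihood
difference can be tested directly with `anova()`.

The probe filter evaluates *model-implied* moments at reference
covariates (age 74, sample-mean sex, country 0; SDs on the country-0
scale). Raw sample moments are a defensible alternative reading of
"expected values"; the model-implied choice matches the filter's intent
(it flags sites whose fitted models are outside the plausible M-value
range) and is recorded in the scan settings.

## The synthetic-data generator

`default_cohorts()` encodes the study conditions the package is
designed around: a Swedish-type cohort (22 MZ + 31 DZ same-sex pairs,
53% female, occasion-1 age drawn Normal(62.9, 7.2) years, 4 pairs with
one twin observed at a single occasion) and a Danish-type cohort
(18 MZ + 25 DZ pairs, 72% female, Normal(76.2, 1.8), complete
observation), both with inter-occasion gaps drawn Uniform(8.00, 11.82)
years and the Danish SDs scaled by k near 0.90/0.88 in the generating
truth. Ages are normal and gaps uniform because only means, SDs and the
gap range are constrained by the design; pair sexes are a single
Bernoulli draw shared by both twins.

`simulate_site()` draws each pair's observed vector from the exact
model-implied multivariate normal, so recovery tests probe the
estimator, not the generator. Per-site seeds derive deterministically
from a master seed, making methylome-scale runs reproducible and
site-parallel. M-values are emitted directly; `m_to_beta()` /
`beta_to_m()` (the log2-ratio transform, with an explicit clipping flag
for boundary Beta-values) convert where Beta-scale output is wanted.

What the generator deliberately does not emulate: probe-level array
artifacts, batch effects, cell-composition signal (removed upstream in
real pipelines), non-Gaussian site distributions, and any dependence
between sites. Passing recovery tests therefore demonstrates that the
estimator inverts the assumed model, not that real methylation data
satisfy that model.

The marginal distribution of true variance shares across a methylome is
unknown, so `simulate_methylome()` takes the truth as an argument (a
fixed truth, a list, or a sampler function) instead of pretending to a
calibrated methylome-wide prior.

## Numerical choices

* Optimizer: L-BFGS-B on the free parameters — variant paths with
  diagonals bounded at zero (the sign convention that makes the
  Cholesky identified), unbounded off-diagonals and mean coefficients,
  scalars bounded below at 1e-4 — with a compiled objective returning
  the negative log-likelihood and its analytic gradient (path, scalar
  and mean derivatives). Gradient projection tolerance 1e-8, up to 400
  iterations, parameter-scaled.
* Starts: a moment-based start (OLS means; per-occasion variances split
  by the empirical MZ/DZ cross-twin covariances of each variant;
  cross paths from the within-person correlation) plus 3 seeded random
  perturbations; nested variants additionally warm-start from reduced
  fuller-variant solutions, which keeps the fitted likelihoods
  monotone across nesting. The best converged solution wins; a start
  whose covariance is numerically singular is pushed away by assigning
  the objective a large finite value.
* Chi-square tests use the naive reference distribution with the
  stated df (6, 3, 3) and no boundary-mixture correction, reproducing
  the standard reporting procedure for this design.
* Degenerate inputs: pairs with no observed slot are rejected at
  assembly; zero total variance flags standardized components
  undefined; identical Fisher-Z inputs are a scale-degeneracy error; a
  single-category contrast returns variance components without a Wald
  test; paired change tests with constant differences return the exact
  degenerate answer instead of erroring.

## Set-level comparisons

Per-site estimates at the two occasions are compared across CpG sets
with a random-intercept linear mixed model, `value ~ membership (+
occasion) + (1 | site)`, fitted by maximum likelihood (not REML) so
Wald chi-square tests on fixed effects are coherent across fits; the
intraclass ratio `rho = var_between / (var_between + var_within)`
measures how much of the variation in estimates is site-specific and
stable across time. The model is fitted with `lme4`, the standard tool
for exactly this fit; recovery of `rho` and the reduction to ordinary
least squares when the between-site variance is zero are tested.

Cross-time correlations are compared between site groups on the
Fisher-Z scale with a skew-normal regression fitted by maximum
likelihood, implemented in the package: the centered parametrization
(mean-scale coefficients, SD, skewness) is optimized for numerical
stability and mapped to the direct parametrization (location, scale,
shape) for reporting. The fitted group mean is the distribution mean —
not the location parameter, which differs whenever the shape is
nonzero — and is inverse-transformed to correlation units by `tanh`.
With the shape fixed at zero the likelihood equals the normal-error
regression, which the suite asserts to 1e-6; non-convergence falls back
to that normal fit, flagged. The group contrast is a likelihood-ratio
test against the no-group model.

## Known limitations

* **The df-3 stability test is conservative.** The test refits the
  best variant with all cross-occasion paths at zero and refers twice
  the log-likelihood difference to chi-square with 3 df. Under
  cross-paths-zero truth the Cholesky parametrization caps each
  source's implied cross-time correlation at |1|; in a large fraction
  of null replicates an occasion-2 diagonal path is estimated at zero,
  the cap binds, and the cross paths cannot use their nominal freedom.
  The statistic is then a boundary mixture stochastically below
  chi-square(3). In a clean single-country design the effect is mild —
  the calibration study in the acceptance suite (400 null sites of 500
  pairs) measures rejection near 0.04 at the 0.05 level — but it is
  more pronounced when weakly-identified per-site nuisance, such as
  the two-country design's free `k1`, `k2` scalars, is estimated
  alongside the paths. Stability p-values should
  therefore be read as conservative, the more so at study scale
  (~100 pairs, two countries): real cross-time signal is, if anything,
  understated. No mixture correction is applied, by design, to keep
  the reported procedure standard.
* A and D (or A and C) are nearly collinear in twin-pair designs; at
  ~100 pairs individual-site A/D splits are noisy and many sites pin
  one source at zero. Broad heritability (A + D) is the stable
  quantity, which is why reporting centres on it and on full-model
  estimates.
* E-dominance diagnostics interpret the empirical-correlation
  indicators (MZ correlation below 0, DZ below -0.05, MZ-DZ difference
  below -0.1) as holding at both occasions; correlations use
  pairwise-complete pairs and need at least two complete pairs per
  zygosity.
* The low-stability rule and classification thresholds are applied to
  the best-fitting variant; a switch for all-variant classification is
  not provided because downstream summaries label the second source
  explicitly instead of pooling C with D.

## Problem sizes in the test suite

The suite validates at sizes chosen to make Monte-Carlo error small
relative to the tolerances while staying desk-scale: 200 sites x 500
pairs for ADE component recovery (tolerance 0.03 on mean standardized
components), 400 null sites for stability-test calibration, 50
parameter draws against a 10-million-draw sufficient-statistic oracle
for the cross-time correlation formulas, 2000 sites for intraclass-
ratio recovery, and the full two-cohort 96-pair design for end-to-end
scans. The pipeline demo runs a smaller methylome so an entire
simulate-fit-classify-summarize cycle stays interactive.
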