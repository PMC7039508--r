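---
title: "Models and methods behind phylodwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylodwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodwell)
```

`phylodwell` tests whether average house floor area (AHFA) and
post-marital residence (PMR) co-evolve across societies while accounting
for their shared history on a phylogeny. This vignette explains the
statistical models, the conventions where the literature leaves a choice
open, what the synthetic-data generator does and does not emulate, and
the numerical details that matter for reproducing results.

## Trait coding

Raw inputs are an area in m² and five Ethnographic-Atlas-style
categorical codes. Every map is total on its documented range and errors
on anything else — silent coercion of a miscoded society would be worse
than a failed run.

* **AHFA**: natural-log transformed. The literature says only
  "log-transformed"; we use base *e* because the base rescales regression
  coefficients but leaves every reported inferential quantity (t/F
  statistics, R², λ, AIC differences) unchanged. The binary split puts
  areas of exactly 65 m² in "large": the documented rule defines "small"
  as strictly below 65 m², so the boundary belongs to the complement
  (`>= 65` ⇒ large). No boundary case need exist in any real sample for
  this to matter.
* **PMR**: the 12-category residence code collapses to a 0–4 ordinal
  "tendency towards matrilocality" (patri/virilocal and avunculocal = 0;
  ambi-virilocal = 1; ambilocal, neolocal, separate and
  avuncu-uxorilocal = 2; ambi-uxorilocal = 3; matri/uxorilocal = 4) and
  to a binary trait that is matrilocal for original codes 5, 9 and 11.
  Downstream the ordinal enters regressions as a numeric predictor — it
  is a graded tendency, not five unordered classes.
* **Material** uses wall material, falling back to roofing material only
  for the "walls indistinguishable from roof" category, where earth/turf
  counts as durable and ice/snow as impermanent; any other combination is
  unresolvable and raises an error rather than guessing.
* **Missing data**: a society missing a variable is dropped only from
  analyses that use that variable, and each result row reports its own
  *n*. No imputation is attempted.

Binary factors are ordered so the "derived" level codes as 1 in model
matrices: large, matrilocal, important agriculture, sedentary, durable.

## Phylogenetic covariance and Pagel's λ

Under Brownian motion the trait covariance of two tips is proportional
to their shared root-to-tip path length, collected in the matrix `C`
(`phylo_vcv()`). Pagel's λ rescales only the off-diagonal of `C`; λ = 1
is the Brownian expectation and λ = 0 removes all phylogenetic
covariance. Trees are *not* assumed ultrametric: applying λ to `C`
rather than to branch lengths keeps the transform well-defined for
non-ultrametric time-calibrated trees, whose tip depths appear on the
diagonal.

`pagel_lambda()` profiles the likelihood of a mean-only multivariate
normal over λ ∈ [0, 1], with the mean and rate σ² profiled analytically.
The 1-D search runs bounded optimization on each quarter of the unit
interval plus explicit endpoint evaluation, with ties broken toward
smaller λ — the profile can be bimodal when signal is weak, and boundary
optima (λ̂ = 0 or 1) are common at realistic sample sizes. Significance
is a likelihood-ratio test against λ = 0 referred to χ²(1); the
boundary-mixture reference (half χ²(0), half χ²(1)) would be mildly more
powerful but we match the convention of the standard tools so p-values
are comparable. With fewer than 4 taxa (or a 2-tip tree, where the
off-diagonal is a single number confounded with σ²) λ is not reliably
identifiable and the function refuses to estimate it.

## Fritz–Purvis D

For a binary trait, nodal values are estimated in one Felsenstein-style
post-order pass: a node's value is the average of its daughters'
values weighted by inverse contrast-extended branch lengths. The
statistic `d` is the sum of absolute sister-clade differences of these
values over internal nodes, and

D = (d_obs − mean d_B) / (mean d_R − mean d_B),

where `d_R` comes from random tip-label permutations and `d_B` from
Brownian simulations thresholded to the observed prevalence (the top *k*
simulated values become 1s, preserving the number of 1s exactly). Any
estimator-specific constant cancels in this scaling as long as the
observed and null `d` use the identical estimator, which they do — the
nodal pass is a fixed linear operator on tip values, so all null
replicates are evaluated by a single matrix product.

Conventions: D is reported *unclipped*. Although it is often described
as lying between 0 and 1, the construction does not bound it — strongly
clumped traits give D < 0 and overdispersed traits D > 1 — and clipping
would destroy the calibration tests. P-values are one-sided toward
clumping: `p_value` is the fraction of permutation `d` at or below
`d_obs`; `p_brownian` the fraction of Brownian `d` at or above it.
Defaults are 1000 permutations and 1000 simulations with a required
seed, recorded in the output, making every D bit-reproducible. Zero or
near-zero branch lengths are floored at 1e-8 of tree depth in the
weighting pass to keep the estimator finite.

## PGLS

`pgls_fit()` estimates `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y` with
`V = λC + (1 − λ)diag(C)` and λ chosen by profile ML on the same
quarter-interval search as above (σ² profiled; ties toward smaller λ).
Conventions the literature leaves open, fixed here and recorded in the
bundle provenance:

* **R²** is defined from Mahalanobis deviances under the fitted
  `V(λ̂)`: `R² = 1 − RSS_V / TSS_V`, where `TSS_V` is the deviance of
  the intercept-only model *at the same λ̂*. Adjusted R² uses the usual
  `1 − (1 − R²)(n − 1)/(n − k_slopes − 1)`; intercept-only models get 0
  by convention.
* **F-test**: the overall regression versus intercept-only at the same
  λ̂, on (k_slopes, n − k) df. At λ = 0 this reduces exactly to
  heteroscedastic weighted OLS (weights 1/diag(C)), which the tests
  verify against `lm()`.
* **AIC** counts the regression coefficients, σ², and λ when λ was
  estimated: `AIC = −2 logL + 2(k + 2)` under ML λ. Absolute AICs are
  convention-dependent; only differences within a table produced under
  one convention are meaningful, which is all the model comparison uses.

`model_table()` fits a list of formulas, reports per-row complete-case
*n*, flags the lowest AIC, and returns rows for failed fits with the
error message instead of aborting the table.

## Ancestral states

`ml_ancestral_continuous()` computes, for each internal node, the GLS
prediction of the node value given the tips and the Brownian
covariance — equivalently the mode of the joint likelihood over all
internal states, which the tests confirm against direct numeric
optimization. The root estimate is the phylogenetic mean
`(1ᵀC⁻¹x)/(1ᵀC⁻¹1)`. Variances are prediction variances with the ML
plug-in σ̂² (no REML correction) and include the uncertainty from
estimating the root mean. Reconstruction of log-area happens on the log
scale, with the root also reported back-transformed to m²; the modal
log-scale estimate back-transforms to the mode on the area scale, not
the mean, and readers should treat the m² figure accordingly. The
residence ordinal is reconstructed with the same continuous machinery —
an approximation (it is a discrete trait) retained because the graded
scale makes the continuous summary interpretable. `branch_gradient()`
exports evenly spaced linear interpolations of the estimates along every
branch, the numeric content of "painted branch" figures.

## Correlated evolution

Two binary traits combine into the 4-state chain over
(0,0), (0,1), (1,0), (1,1); simultaneous change of both traits has rate
0 structurally. Models: independent (each trait's gain/loss rates ignore
the other trait; 4 free rates), dependent (all 8 permitted rates free),
and the one-way models dep_x/dep_y (6 rates each) in which only one
trait's rates respond to the other's state. The likelihood is
Felsenstein pruning with `P(t) = exp(Qt)`, implemented in C++ via one
eigendecomposition of the 4×4 generator per likelihood evaluation (with
a Padé fallback if the generator is defective) and per-node rescaling —
this is the hot loop of the whole package, evaluated millions of times
in the calibration experiments.

Conventions: the root prior is flat (1/4 each) by default, with a
stationary-distribution option; the flat prior keeps the
independent-model likelihood exactly equal to the product of the two
single-trait 2-state likelihoods (a tested identity). Branch lengths
are used as given. Rates are optimized on the log scale within
[1e-6, 100] per unit branch length, from one deterministic start (about
two expected changes per tree depth) plus random restarts (10 by
default, seeded); `pagel_test()` warm-starts each richer model from its
nested solutions, so the likelihood nesting
independent ≤ dep_x/dep_y ≤ dependent holds to optimizer tolerance. The
headline test refers 2·(logL_dep − logL_indep) to χ²(4), matching the
8 − 4 parameter-count difference; the AIC table over all four models
addresses *which* trait responds to the other.

## Synthetic studies

`simulate_study()` generates the conditions the analysis assumes, with
known ground truth:

* a pure-birth tree rescaled to unit depth (topology beyond "a valid
  ultrametric tree" is irrelevant to the statistics being tested);
* residence as a 5-state nearest-neighbour chain (jumps of ±1 only, so
  the ordinal scale is meaningful), upward rate 2 and downward 0.5 per
  unit depth from a patrilocal root — chosen once, by computing the
  transient distribution `exp(Q·1)` analytically, to put roughly a
  quarter of societies in the matrilocal states (echoing 22 of 86) with
  a realistic spread over the intermediate states;
* settlement, agriculture and material as 2-state chains (gain/loss
  2/0.5, 1.5/0.5 and 1/1) giving sedentary/important majorities and
  moderate phylogenetic clumping;
* log house area as
  `β₀ + β₁·pmr_ord + β₂·settlement + BM(λ, σ²)` with defaults
  β = (ln 15, 0.26, 0.83), σ² = 0.5, λ = 0.1 — effect sizes set so
  settlement explains roughly 16% and residence roughly 10% of log-area
  variance over weakly structured residuals, the magnitudes typical of
  cross-cultural dwelling-size data;
* coded values inverse-mapped to representative raw codes (ordinal 4 →
  EA012 code 5, sedentary → EA030 code 7, ...), with every eighth
  society expressing material through the EA081 = 11/EA083 roofing
  fallback, so the coding module round-trips exactly.

If any binary variable comes out monomorphic the categorical traits are
redrawn, up to 100 attempts; prevalences are steered by root states and
rates, never forced by rejection to exact counts. What the generator
does *not* emulate: geography and areal diffusion, language-family
structure, measurement error in ethnographic records, missing-data
patterns, or realistic supertree calibration depths. Passing tests
therefore demonstrate that the estimators recover the generating
process under the model's own assumptions — not that those assumptions
hold for real ethnographic data.

## Numerical choices and degenerate inputs

* Covariance solves go through Cholesky; if a matrix is numerically
  singular (e.g. zero-length terminal branches, which `validate_tree()`
  warns about) a 1e-10·mean-diagonal ridge is added with a loud warning.
* λ searches snap near-boundary optima to the exact boundary when the
  boundary value is at least as good, so λ̂ = 0 and λ̂ = 1 are reported
  exactly.
* Zero-rate chains assign −∞ log-likelihood to impossible data rather
  than failing.
* All simulators take seeds and restore the caller's RNG state; the
  pipeline derives per-stage seeds from one master seed, making a full
  run byte-reproducible (verified in the tests by comparing written
  bundles).

## Problem sizes used in validation

The test suite validates at the scales the estimators are meant for
while keeping a full run in the minutes range: exact-oracle equivalence
on 3–10-taxon problems; λ recovery (mean absolute error ≤ 0.15) on
200-tip trees, 50 replicates per true λ ∈ {0, 0.5, 1}; regression slope
recovery on 200 replicated 86-society studies; likelihood-ratio type-I
error over 500 independent-model simulations and power over 100
strong-dependence simulations on 200-tip trees; D calibration on 64-tip
trees with 1000-replicate nulls (100 Brownian-threshold and 50 shuffled
traits). The observed type-I rate of the χ²(4) test at these sizes sits
near 0.06 — close to, and slightly above, the nominal 0.05, consistent
with the known mild anticonservatism of the likelihood-ratio reference
for this model family at finite tree sizes.

## Known limitations

* λ estimation at n ≈ 86 is noticeably biased toward the boundaries;
  residual-λ̂ averages recovered in simulation sit a little below the
  generating value. Model *rankings* are robust to this; absolute λ̂
  values at this sample size should be read with care.
* The D statistic's Brownian null assumes the threshold model; traits
  generated by other clumping mechanisms calibrate differently.
* Continuous-machinery reconstruction of the residence ordinal ignores
  its discreteness.
* PGLS assumes a single λ for the residuals; alternative correlation
  structures (Ornstein–Uhlenbeck, ...) are out of scope.
* The correlated-evolution test conditions on the tree and dichotomized
  traits; dichotomization discards within-category variation in both
  house size and residence.
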