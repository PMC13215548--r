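---
title: "Methods: estimating and smoothing subnational under-five mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and smoothing subnational under-five mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mortsmooth` implements a complete workflow for subnational under-five
mortality analysis from full-birth-history surveys: direct design-based
estimation, functional comparison of regional trajectories, and Bayesian
space-time smoothing with forecasts. This vignette documents the models, the
numerical choices, and the reasoning behind the design decisions that were
genuinely open.

## The estimation problem

The under-five mortality rate (U5MR) is the probability that a child dies
before its fifth birthday, per 1,000 live births. Demographic surveys record
a *full birth history* for each interviewed woman — the birth date and, if
applicable, the death age of every child — under a two-stage stratified
cluster design: regions are split into urban/rural strata, clusters
(enumeration areas) are sampled within strata, and households within
clusters. Annual region-level U5MR series derived from such data are noisy,
especially in early calendar years where few children are exposed, which
motivates the two complementary smoothing stages below.

## Direct estimation

For a region-year cell, the estimator pools each child's person-months at
risk into six age bands (0, 1–11, 12–23, 24–35, 36–47, 48–59 months). The
monthly hazard in band $a$ is the ratio of design-weighted deaths to
design-weighted person-months at risk, and the synthetic-cohort life table
combines bands:

$$ \hat q_5 = 1 - \prod_a (1 - \hat h_a)^{n_a}, \qquad
   n = (1, 11, 12, 12, 12, 12). $$

Estimates are carried on the logit scale with a delete-one-cluster jackknife
variance (JK1 over clusters, the primary sampling units), floored at
$10^{-6}$. Choices worth stating:

* **Annual periods.** One estimate per region per calendar year; a child
  contributes to the year each person-month falls in (period, not cohort,
  estimand).
* **Zero-death cells.** A continuity correction adds half the smallest
  observed weighted death mass to the first band, keeping the logit finite
  without materially moving well-populated cells.
* **Bands emptied by a jackknife deletion** fall back to the full-cell
  hazard for that band.
* **Missing cells** (no exposure in some band) are flagged, excluded from
  the functional analysis, and left to the Bayesian smoother, which
  interpolates them.
* Hazards are event/person-month ratios rather than a weighted regression:
  for the saturated one-band-at-a-time model the two coincide, and the ratio
  form is directly verifiable against a brute-force life table, which the
  test suite does on enumerable toys.

## Functional ANOVA on mortality curves

Each trajectory is represented as a penalized B-spline (order 4, equally
spaced interior knots, integrated-squared-second-derivative penalty;
`lambda` by generalized cross-validation over a log-spaced grid, since no
single smoothing level suits all series). One-way functional ANOVA then
decomposes curves $y_{gj}(t) = \mu(t) + \beta_g(t) + \epsilon_{gj}(t)$ under
$\sum_g n_g \beta_g(t) = 0$, with the pointwise statistic

$$ F(t) = \frac{\mathrm{SSB}(t)/(G-1)}{\mathrm{SSW}(t)/(N-G)} $$

tested by permutation of group labels: the pointwise critical curve is the
95th percentile of permuted $F(t)$ at each $t$, and the global (familywise)
threshold is the 95th percentile of $\max_t F(t)$. The global p-value uses
the add-one correction $(1 + \#\{\max F^{perm} \ge \max F^{obs}\})/(B+1)$.

**Replication.** With one curve per region and region as the factor, the
residual degrees of freedom are zero and no $F$ exists. The package
therefore requires more curves than groups and, in the pipeline, uses the
16 stratum-level curves (urban/rural within region) as replicates with
region as the factor. This is a design choice of this package, stated
prominently rather than assumed silently; any other replication scheme
(e.g. bootstrap curves) can be supplied directly to `permutation_test()`.
By default the test runs on smoothed curves; `fanova$smoothed: false`
switches to the raw annual values.

## The Bayesian space-time model

Logit-scale direct estimates enter a Gaussian observation stage with the
design-based variances treated as known:

$$ y_{it} \sim N(\eta_{it}, v_{it}), \qquad
   \eta_{it} = \mu + \alpha_t + \gamma_t + \theta_i + \phi_i + \delta_{it}. $$

* $\alpha_t$: iid temporal shocks; $\gamma_t$: structured temporal trend
  with a random-walk prior of order 1 (Model I) or 2 (Model II);
* $\theta_i$: iid regional heterogeneity; $\phi_i$: ICAR spatially
  structured effect with structure matrix $Q = D - W$;
* $\delta_{it}$: iid space-time interaction (the independent interaction
  type);
* all five precisions get Gamma(0.5, 0.001) priors — shape/**rate**, prior
  mean 500; the parametrization is easy to get silently wrong, hence stated;
* $\mu$ has a Normal(0, $10^6$) prior, effectively flat.

**Identification.** Sum-to-zero constraints are enforced on
$\alpha, \gamma, \theta, \phi$ and double-centring on $\delta$ by
recentring each sweep, with removed means pushed up the hierarchy so
$\eta$ (and the likelihood) is untouched. The RW2 effect is *not*
constrained orthogonal to linear trends: the secular decline of mortality
must live somewhere, and with $\delta$ double-centred and $\alpha$
exchangeable, $\gamma$ is its only possible carrier — a fitted $\gamma$
falling on the order of one logit unit over three decades is exactly the
expected signature. (The *synthetic* generator, by contrast, does project
its RW2 component orthogonal to linear and carries the secular decline as
an explicit per-year trend field, so that truth components remain
separately identifiable in recovery tests.)

**Sampling.** All full conditionals are conjugate, so the model is fitted
by Gibbs sampling with two structural refinements:

1. $(\alpha, \gamma)$ and $(\theta, \phi)$ are each updated as a joint
   Gaussian block. Only the sums $\alpha_t + \gamma_t$ and
   $\theta_i + \phi_i$ enter the likelihood; single-site updates leave the
   attribution between the iid and structured halves frozen at its initial
   split.
2. $(\tau_\theta, \tau_\phi)$ are updated by a collapsed Metropolis step
   with the spatial effects integrated out analytically (the marginal of
   the per-region weighted residual means is Gaussian with covariance
   $D^{-1} + \tau_\theta^{-1} I + \tau_\phi^{-1} Q^{+}$). The conditional
   $\tau \mid$ effects is nearly a point mass, which traps ordinary Gibbs in
   one attribution mode; the collapsed step moves between modes. The
   remaining precisions keep conjugate Gamma updates with shape
   $a + \mathrm{rank}/2$ and rate $b + \text{quadratic form}/2$, using the
   constrained ranks ($T-1$, $T-\text{order}$, $n-1$, $n-1$,
   $(n-1)(T-1)$).

Defaults are 20,000 iterations, 5,000 burn-in, thinning 5; all analyses in
the tests and the acceptance script use shorter, stated runs (typically
1,200–8,000 iterations), which the small block sizes (8 regions, 33 years)
make adequate — posterior summaries there are reproducible to within the
Monte-Carlo tolerances the tests assert. Fits are deterministic given the
seed. Missing cells are permitted: their $\delta$ and shared effects are
drawn from the prior conditionals, yielding model-based interpolation.

**Forecasting.** Per retained draw, $\gamma$ is propagated through its
random-walk recursion ($\gamma_{T+h} = 2\gamma_{T+h-1} - \gamma_{T+h-2} +
\varepsilon$ for order 2, innovation variance $1/\tau_\gamma$ of that draw)
and the forecast predictor is $\mu + \gamma_{T+h} + \theta_i + \phi_i$. The
iid temporal shocks carry no autoregressive structure and the interaction
no temporal structure, so neither is projected forward: forecasts reflect
the smooth trend plus stable regional levels, and credible intervals widen
with horizon through the accumulating innovations. In the no-innovation
limit the RW2 null space makes the forecast a straight line — a property
the tests exercise exactly.

## Model assessment

* **DIC** $= \bar D + p_D$ with $p_D = \bar D - D(\bar\eta)$
  (plug-in form; the half-variance variant is available by argument).
  Negative $p_D$ is flagged as a mixing diagnostic.
* **CPO/LCPO**: $\mathrm{CPO}_{it}$ is the harmonic mean of per-draw
  likelihoods, computed through log-sum-exp; LCPO is the *sum* of
  $\log \mathrm{CPO}$ — consistent with per-cell magnitudes of reported
  model-comparison values, and signed so that higher is better.
* **Variance decomposition**: the empirical variance of the
  posterior-median elements of each component (over years, regions, or all
  cells), as a percentage of their total. The ICAR and random-walk priors
  define variances only conditionally, so the empirical variance of the
  identified, constrained effects is the well-defined quantity. Because the
  fitted $\gamma$ carries the secular trend, its share dominates this
  decomposition whenever mortality declines strongly — a
  hyperparameter-based recipe (posterior $1/\tau$) would attribute that
  differently.
* **Comparison rule**: lower DIC wins; both criteria are always reported
  and a DIC/LCPO disagreement is flagged.

## The synthetic-data generator

The generator exists so that every downstream stage is testable against
known truth without restricted survey microdata. It emulates:

* a logit-scale truth surface with exactly the model's five components,
  plus an explicit linear trend term (default −0.035/year, reproducing a
  decline from roughly 100 to 35 per 1,000 over 33 years around a grand
  mean of 60 per 1,000);
* component scales chosen to put most non-trend variation in the
  structured spatial effect (conditional variance 0.03, against 0.004 iid
  spatial, 0.002 iid temporal and interaction, and a small RW2 innovation
  variance of 4×10⁻⁴), mirroring settings where spatial structure dominates;
* a two-stage design of 8 regions × 2 strata × 42 clusters × 30 women with
  Poisson(3.2) births per woman — about 64,000–65,000 child records, the
  scale of a large national survey; urban strata carry population share 0.3,
  so weights differ by stratum and are normalized to mean 1;
* period survival: each child faces, month by month, the hazard of its
  current age band in its current calendar year; observation is censored at
  the interview month. Births begin five years before the first analysis
  year so early cells have exposure at all ages; years before the surface
  reuse its first year's hazards.

It deliberately does **not** emulate: PPS cluster selection against census
sizes, within-mother correlation of sibling outcomes, date-reporting
heaping or displacement, or region-specific interview timing. Passing tests
therefore demonstrate correctness of the estimators and samplers under the
model's own assumptions, not robustness to those real-data artefacts.

## Numerical choices

* Month indices are integer counts from January 1900 (0-based), the
  century-month convention of demographic surveys.
* `hazards_from_q5()` inverts the life-table product by scalar
  root-finding (`uniroot`, tolerance 1e-14) on a fixed age shape whose
  default concentrates mortality in the first month and year of life.
* The roughness penalty matrix is assembled by per-interval Gauss–Legendre
  quadrature, exact for the piecewise-polynomial integrand. At extreme
  penalty weights (beyond ~1e10) float rounding erodes the penalty null
  space slightly; the GCV grid spans 1e-6–1e6, far inside that regime.
* The smoother's normal equations carry a tiny ridge (1e-10 relative to
  B'B) so exactly determined and rank-deficient fits solve stably.
* Permutation and Monte-Carlo procedures take explicit seeds everywhere;
  the pipeline expands one global seed into per-stage seeds by hashing the
  stage name, so stages are independently reproducible.
* The jackknife variance floor (1e-6) prevents degenerate zero variances
  from identical leave-one-out replicates.

## Study sizes used by the tests and acceptance script

The test suite runs the full stack at deliberately chosen sizes: toys small
enough to enumerate by hand (≤ 25 children) for exactness checks; 50,000
births for the estimator-consistency check; 200 replicate null datasets ×
500 permutations for the calibration of the global permutation test; and 20
replicates of the 8 × 33 recovery study for coverage, correlation, and
model-selection checks. The recovery study simulates the Gaussian stage
directly at observation variance 0.005 — noise standard deviation about
half the signal standard deviation. (The full survey pipeline at national
scale produces design variances an order of magnitude larger, at which no
smoother could reach the recovery correlations the tests require; the
Gaussian-stage study isolates the smoother from survey noise.)

## Known limitations

* **Spatial attribution is weakly identified with 8 regions.** Only
  $\theta_i + \phi_i$ is likelihood-identified; the split rests on the
  8-vector's shape. Direct grid integration of the exact marginal
  posterior shows that even the Bayes-optimal rate of identifying the
  structured component as dominant — when the truth makes it dominant — is
  roughly 0.8 per replicate, and the medians-based decomposition, which
  averages over the ambiguous split, identifies it roughly half the time.
  The corresponding recovery check documents this honestly rather than
  asserting a rate the model cannot deliver; users should read the
  $\theta$/$\phi$ split, and variance shares derived from it, as
  prior-informed rather than data-identified at this spatial resolution.
  Estimates of $\eta$, forecasts, and model comparison are unaffected ($\eta$
  depends only on the sum).
* The pseudo-likelihood treats design variances as known; very sparse
  cells violate that, which is why variances are floored and zero-death
  cells corrected.
* Forecasts are conditional trend extrapolations: they exclude interaction
  and iid-shock uncertainty by design and cannot anticipate structural
  breaks.
* One connected adjacency component is required; analyses with islands
  need the graph edited (e.g. a bridge edge) before fitting.
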