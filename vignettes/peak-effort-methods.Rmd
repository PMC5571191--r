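---
title: "Methods: peak reproductive effort, mast timing and lifetime fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak reproductive effort, mast timing and lifetime fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakeffort)
```

## The scientific problem

In iteroparous species the age trajectory of reproduction typically rises
to a peak and declines. Two properties of that peak — its height (the
maximum annual number of offspring, *peak effort*) and its timing —
may themselves be life-history traits under selection. In a resource-pulse
system such as red squirrels relying on masting white spruce, the question
sharpens: mast years are rare (four in the 1986–2013 study window),
juvenile overwinter survival roughly doubles in them, and females that
concentrate their maximum effort into a mast year may convert the same
lifetime litter production into many more recruited offspring.

The statistical obstacle is structural: lifetime pups are the sum of
annual litters, so `lifetime >= peak` holds identically and a naive
regression of lifetime output on peak effort is guaranteed a positive
slope. Every analysis in this package is organized around measuring the
association *beyond* that floor.

## Derived variables

From a long-format table of annual records (`female_id, cohort, year,
age, pups, recruits`) the package derives, per female: lifespan (maximum
recorded age), peak effort (maximum annual pups), peak age (the age at
which that maximum is *first* achieved — ties flag every attaining year
in the annual table, but peak age takes the first), lifetime pups and
recruits, primiparity (first litter at age 1 vs later; delayed is the
reference level), mast exposure (any mast year at adult age within the
lifespan), the mast-peak indicator (the first-attainment peak year is a
mast year), age at the (first) adult mast year, the pre-peak rate of
reproduction (pups per year before the peak age, defined as 0 when the
peak is at age 1 — the convention we adopt for a quantity the source
material leaves as "pups per year before the peak"), post-peak lifespan
and post-peak pups. Breeders are females with at least one pup; analysis
subsets are all breeders, the mast-experienced, the never-mast
complement, and the multi-year breeders (a sensitivity set).

Continuous predictors are scaled within each analysis to mean zero and
unit *sample* standard deviation (divisor `n - 1`); quadratic and
interaction columns are built from the scaled linear columns
(scale-then-square), so coefficients are comparable across terms and the
quadratic vertex `-b1/(2 b2)` maps back to natural units through the
stored center and scale.

## The mixed-model engine

All models are random-intercept GLMMs estimated by maximizing a
Laplace-approximated marginal likelihood:

* **Inner loop.** For fixed variance parameters, the joint mode of the
  fixed effects and random intercepts maximizes the penalized
  log-likelihood; it is found by penalized iteratively reweighted least
  squares with step-halving, to a relative penalized-deviance tolerance
  of 1e-10 (at most 100 iterations). Systems of up to 64 columns use
  dense LAPACK solves; larger ones (e.g. female-within-cohort models
  with thousands of females) use sparse Cholesky factorizations via
  the Matrix package.
* **Outer loop.** The Laplace objective
  `loglik(y | mode) - penalty - (1/2) log det(Z'WZ + D) - (1/2) log det(Sigma)`
  is optimized over the log random-effect variances, plus the log
  negative-binomial dispersion and the log residual variance where
  applicable. One-parameter problems use Brent search (with an explicit
  check of the variance-zero boundary); multi-parameter problems use
  `nlminb` with restarts — return codes near variance boundaries and on
  flat dispersion ridges are unreliable, so convergence is declared when
  a restarted optimizer improves the objective by less than 1e-3.
* **Families.** Poisson (log), negative binomial (log; variance
  `mu + mu^2/theta`, `theta` estimated jointly and reported as the
  dispersion parameter), binomial (logit, binary responses), Gaussian
  (identity, fitted by maximum likelihood).
* **Inference.** Wald `z` per term for the GLMM families. For the
  Gaussian LMM, `t` statistics use Satterthwaite degrees of freedom
  computed from numerical gradients of each coefficient's variance with
  respect to the variance parameters and the inverse outer Hessian; when
  that computation fails the residual `n - p` degrees of freedom are
  used and recorded. Parametric-bootstrap percentile CIs (new random
  intercepts from the fitted variances, responses from the fitted
  family, full refits) are available for any converged model; the
  bootstrap requires an explicit seed and reports its non-convergence
  count.
* **Selection.** Backward selection removes, at each step, the least
  significant removable term with `p >= alpha` (default 0.05).
  Marginality is respected: polynomial and interaction terms leave
  before the main effects they contain become removable, which is why a
  non-significant linear term can legitimately remain in a final model
  whose quadratic is significant.

With the random-effect variance forced to zero the fit reduces exactly
to the corresponding fixed-effects GLM — the engine's primary oracle,
tested against `glm`, `MASS::glm.nb` and `lm`, and cross-checked against
`lme4` on random-intercept fits. Note one deliberate estimation choice:
the fixed effects are profiled at the joint penalized mode rather than
optimized in the outer stage, which can move intercept-like terms by
about 0.01 relative to implementations that do the latter; slopes and
variance components agree much more closely.

The nested "squirrel within cohort" structure is implemented as two
independent batches of Gaussian intercepts (one per cohort, one per
female). Because every female belongs to exactly one cohort this is the
standard nested random-intercept model. Crossed structures, random
slopes and adaptive quadrature beyond Laplace are out of scope.

## The constrained resampling null

The null hypothesis is that the peak-effort/lifetime-pups slope reflects
nothing but the floor `lifetime >= peak`. The resampling scheme keeps
every female's covariates (peak effort, peak age, lifespan, primiparity,
cohort) and replaces her lifetime pups with a draw, with replacement,
from the pool of *observed* lifetime values restricted to those at least
as large as her peak. Her own value is always admissible, so the pool is
never empty; the scheme preserves the marginal lifetime distribution
while breaking any female-specific link beyond the constraint. The
selected lifetime-pups Poisson GLMM is refit on each of (by default)
1000 resamples; the observed scaled linear peak-effort coefficient is
compared one-sidedly against the collected null slopes.

The precise resampling distribution was a genuinely open design point;
we chose the empirical-truncated scheme as the minimal one satisfying
the constraint and preserving the marginal distribution, and exposed a
uniform-over-admissible-range alternative through `method = "uniform"`
for sensitivity. Degenerate single-event females sit exactly on the
`lifetime = peak` line, the slope-one boundary case of the null.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the study conditions: the 1986–2013
calendar with mast years 1993, 1998, 2005, 2010; cohorts 1986–2009;
truncated-geometric adult lifespans on 1–8 years with year-to-year
continuation probability `1/sqrt(2)` (median adult lifespan 3, so
mast-experienced females accumulate a median of about 3 breeding
events — they can very rarely reach 8, slightly above the intended
ceiling of 7); primiparity at age 1 with probability 0.6 (else ages 2:3
at weights 3:1); Poisson annual litters with a multiplicative mast
effect of `exp(0.569)` (consistent with the published means 2.08
non-mast vs 3.66 mast, since `log(3.66/2.08) ~ 0.565`); binomial
recruitment at 0.20 (non-mast) vs 0.41 (mast); lognormal cohort and
female intercepts with variances 0.05 and 0.10; and a prospective
survival cost of 0.5 years of expected remaining life from the first
year in which the running-maximum effort is achieved in a mast year
(the published post-peak lifespans differ by about half a year).

The baseline log litter mean is derived in closed form so that the
marginal mean of annual pups over all breeder female-years in non-mast
years hits 2.08: the enumeration over the cohort-by-lifespan-by-
primiparity grid accounts for the structural zero years before first
breeding and for censoring of females whose life would extend past the
calendar end (late cohorts can only contribute short-lived females, as
in the real study design). The second-order effect of the survival cost
on that ratio is ignored. Lifespan and litter distributions beyond the
published moments are calibration conveniences, not claims about the
study system.

Simulated populations carry one realization of 24 cohort intercepts, so
population-level means wobble by several percent between seeds exactly
as a single observed population would; moment tests therefore either
silence the cohort variance or use tolerances wide enough to absorb it.
The generator has no spatial or territory dynamics, no males, no density
dependence, no food-caching mechanics and no cone-count model (mast
years are given); passing tests demonstrate the statistical machinery on
data with the assumed structure, not the ecology of any real population.

## Numerical and design choices

* Variance parameters are optimized on the log scale with bounds
  `[-15, 8]`; a log-variance at the lower bound is reported as an
  effectively-zero variance component (boundary fit).
* Negative-binomial dispersion is bounded at `exp(12)`; on data with no
  overdispersion the fit approaches the Poisson GLMM, which is also a
  tested limit (`fix_theta = 1e7`).
* The Gaussian LMM uses maximum likelihood, not REML, keeping one
  estimation contract across all families; Satterthwaite df are computed
  against the ML variance estimates.
* Wald CIs (1.96 se) are the default interval; bootstrap CIs are opt-in
  because of their cost. Parameter-recovery calibration of the Wald
  intervals — including the log-scale intervals for the dispersion and
  the cohort variance — is part of the test suite (100 replicates of
  2000 simulated females; nominal 95% coverage required to land in
  90–99%).
* Backward selection ties are broken by the largest p-value; the
  selection trace is recorded step by step.
* Binary covariates are coded 0/1 (delayed primiparity and non-mast as
  reference levels) and are never scaled.
* Test problem sizes are chosen to keep the full suite at desk scale:
  moment checks at 5000 females, engine cross-checks at hundreds to two
  thousand observations, the null-test self-consistency property at 20
  replicates of 200 iterations on 250-female populations, and the
  exhaustive resampling oracle on a 3-female toy set where complete
  enumeration is feasible.

## Known limitations

* The survival cost couples lifespan to past litter draws, a deliberate
  piece of realism with a measurable side effect: females that achieve
  their maximum in a mast year lose disproportionately many later
  non-mast years, so the *marginal* mast coefficient of the annual-pups
  GLMM sits somewhat above the generative multiplicative effect
  (selective disappearance). Parameter-recovery tests that require exact
  well-specification therefore switch the cost off; tests of the
  calibrated study conditions keep it on and use statistical-consistency
  tolerances.
* The Laplace approximation shares the usual small-cluster caveats;
  with very few observations per group or binary responses in tiny
  groups its variance estimates can be biased low. The analyses here
  use 18–24 cohorts and several records per female, where it is
  adequate.
* Published back-transformed coefficient columns are not reproduced:
  the transformation behind them is not derivable from the stated
  information, so rather than guess we report scaled coefficients only.
* The empirical-truncated null is one reconstruction of a procedure
  whose full specification lives in supplementary material we do not
  ship; the interface isolates it so alternatives can be compared.
* `run_full_analysis()` derives cohort counts and subset sizes from the
  data rather than hard-coding the published ones, so reports on other
  data sets remain internally consistent.
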