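# peakeffort

Life-history analysis of **peak reproductive effort** in a resource-pulse
(masting) system.

Iteroparous females do not spread reproduction evenly over life: annual
output rises to a peak and declines. In populations of North American red
squirrels living off mast-seeding white spruce, the "height" of that peak
(the maximum annual number of pups, *peak effort*) and its timing relative
to a mast year carry most of a female's lifetime reproductive success.
Quantifying that dependence is statistically delicate for one obligate
reason: lifetime pups can never be fewer than the largest annual litter,
so lifetime output and peak effort are positively related by construction.

This package provides, for ecologists studying individual life-history
variation:

* **A calibrated individual-based simulator** of female life histories
  (`sim_config()`, `simulate_population()`): truncated-geometric adult
  lifespans, yearling-vs-delayed primiparity, Poisson (or
  negative-binomial) annual litters with a multiplicative mast effect and
  cohort/female lognormal heterogeneity, binomial recruitment with
  mast-dependent survival, and a prospective survival cost of peaking in
  a mast year.
* **Derived life-history variables** (`summarize_females()`,
  `annual_table()`, `build_analysis_sets()`): peak effort, peak age
  (first attainment), lifetime totals, primiparity, mast exposure,
  mast-peak indicator, pre-peak rate, post-peak lifespan and output.
* **A random-intercept GLMM engine written in this package**
  (`fit_glmm()`, `laplace_glmm()`): Poisson, negative-binomial, binomial
  and Gaussian families estimated by Laplace approximation with a
  penalized-IRLS inner loop and sparse linear algebra, plus Wald tests
  (Satterthwaite *df* for the Gaussian LMM), backward selection under
  marginality (`backward_select()`), parametric-bootstrap CIs
  (`bootstrap_ci()`), predicted curves and quadratic optima
  (`predict_curve()`, `vertex_in_natural_units()`).
* **A constrained resampling null test** (`constrained_resample()`,
  `null_slope_distribution()`): the peak-effort slope is compared against
  the distribution obtained when each female's lifetime output is redrawn
  only from observed values satisfying `lifetime >= her peak effort` —
  the null implied by the floor constraint alone.
* **A pipeline** (`run_full_analysis()`) fitting the full set of nine
  mixed models (lifetime pups/recruits, peak-year timing, annual
  pups/recruits vs mast, mast-peak fitness, age-at-mast constraint,
  post-peak survival and reproduction), descriptive group statistics and
  sensitivity reruns.

## The model at the core

For female *i* of cohort *c*, lifetime pups are modelled as

```
y_i ~ Poisson(mu_i)
log mu_i = b0 + b1 * peak_i + b2 * peak_i^2 + b3 * age_i + b4 * age_i^2
           + b5 * lifespan_i + b6 * primiparity_i + u_c,   u_c ~ N(0, s2_c)
```

with all continuous predictors scaled to zero mean and unit sd within the
analysis (lifetime recruits use a negative-binomial family, variance
`mu + mu^2/theta`). A negative `b2` puts the optimum effort at the scaled
vertex `-b1 / (2 b2)`, mapped back to pups through the scaling constants.
The observed `b1` is then referred to the constrained-resampling null
distribution above.

## Worked example

```r
library(peakeffort)

cfg <- sim_config(n_females = 300, seed = 42)
records <- simulate_population(cfg)
cal <- default_calendar()
summaries <- summarize_females(records, cal)
sets <- build_analysis_sets(summaries)

spec <- model_spec(
  "lifetime_pups",
  c("peak_effort", "peak_effort^2", "peak_age", "peak_age^2",
    "lifespan", "primiparity"),
  family = "poisson", random = "cohort")
sel <- backward_select(spec, sets$full)
sel$fit
```

```
poisson GLMM (log link), N = 247
Response: lifetime_pups
          term estimate     se statistic  p_value
   (Intercept)   1.7063 0.0440     38.78 0.00e+00
   peak_effort   0.5899 0.0351     16.78 3.18e-63
 peak_effort^2  -0.0650 0.0107     -6.06 1.33e-09
      peak_age   0.0318 0.0456      0.70 4.86e-01
    peak_age^2  -0.0520 0.0175     -2.97 3.01e-03
      lifespan   0.4112 0.0300     13.70 1.01e-42
   primiparity   0.2759 0.0531      5.20 2.03e-07
Random-effect variances: cohort = 3.059e-07
Log-likelihood (Laplace): -497.019
```

Lifetime output rises steeply with peak effort (scaled slope 0.59) but
with a significantly negative quadratic: the payoff saturates at high
annual litters. The non-significant linear peak-age term stays in the
model because its quadratic is significant (marginality). The cohort
variance collapses to the boundary on this draw.

```r
vertex_in_natural_units(sel$fit, "peak_effort")$natural
#> [1] 14.75  # pups: the annual effort with the largest predicted payoff

null_slope_distribution(sets$full, sel$spec, n_iterations = 200,
                        seed = 42)
```

```
Constrained-resampling null test (lifetime pups >= peak effort)
  observed slope (peak_effort): 0.5899
  null slopes (200 iterations, 0 failed): mean 0.2052, range 0.0342 to 0.3992
  one-sided empirical p: 0
```

The floor constraint alone produces clearly positive null slopes (mean
0.21) — yet the observed slope exceeds every one of the 200 null
refits: the peak-effort/lifetime-output association is not an artifact
of the constraint.

The single call
`run_full_analysis(records, cal, config = list(seed = 42))` fits all
nine models, the optima, the descriptives and the null test at once.

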