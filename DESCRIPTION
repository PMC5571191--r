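Package: peakeffort
Title: Fitness Consequences of Peak Reproductive Effort in Resource-Pulse
    Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how the magnitude and timing of an
    iteroparous female's peak reproductive effort shape her lifetime
    reproductive success in a masting (resource-pulse) system.  Provides a
    seeded individual-based simulator of female red-squirrel life histories
    calibrated to published population moments, derivation of per-female
    life-history variables (peak effort, peak age, lifetime output,
    mast-peak indicators, post-peak metrics), a random-intercept
    generalized linear mixed model engine (Poisson, negative binomial,
    binomial, Gaussian) estimated by Laplace approximation with penalized
    iteratively reweighted least squares, backward model selection,
    parametric-bootstrap confidence intervals, predicted-curve and
    quadratic-optimum utilities, a constrained resampling null test for
    the peak-effort/lifetime-output slope under the obligate constraint
    lifetime pups >= peak effort, and a pipeline reproducing the full set
    of mixed-model analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
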