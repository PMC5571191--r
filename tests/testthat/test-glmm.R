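# Engine checks: boundary equivalence with fixed-effects GLMs, agreement
# with an independent mixed-model implementation, and parameter recovery.

test_that("variance-zero fits reproduce fixed-effects GLMs", {
  d <- make_poisson_glmm_data(n = 300, seed = 11)
  sp <- model_spec("y", "x", family = "poisson", random = "cohort",
                   scale_vars = character(0))
  ours <- fit_glmm(sp, d, glmm_control(fix_variance = 0))
  ref <- glm(y ~ x, data = d, family = poisson)
  expect_lt(max(abs(coef(ours) - coef(ref))), 1e-4)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)

  set.seed(21)
  d$z <- rbinom(nrow(d), 1, plogis(-0.3 + 0.7 * d$x))
  spb <- model_spec("z", "x", family = "binomial", random = "cohort",
                    scale_vars = character(0))
  oursb <- fit_glmm(spb, d, glmm_control(fix_variance = 0))
  refb <- glm(z ~ x, data = d, family = binomial)
  expect_lt(max(abs(coef(oursb) - coef(refb))), 1e-4)

  set.seed(22)
  d$w <- 1 + 0.5 * d$x + rnorm(nrow(d))
  spg <- model_spec("w", "x", family = "gaussian", random = "cohort",
                    scale_vars = character(0))
  oursg <- fit_glmm(spg, d, glmm_control(fix_variance = 0))
  refg <- lm(w ~ x, data = d)
  expect_lt(max(abs(coef(oursg) - coef(refg))), 1e-4)
  # ML residual variance, not the n-p denominator
  expect_equal(oursg$sigma2, mean(resid(refg)^2), tolerance = 1e-5)
})

test_that("negative-binomial fixed-effects fit matches glm.nb", {
  skip_if_not_installed("MASS")
  set.seed(31)
  n <- 800
  x <- rnorm(n)
  y <- rnbinom(n, size = 5, mu = exp(1 + 0.6 * x))
  d <- data.frame(y = y, x = x, cohort = rep(1:10, each = 80))
  sp <- model_spec("y", "x", family = "negative_binomial",
                   random = "cohort", scale_vars = character(0))
  ours <- fit_glmm(sp, d, glmm_control(fix_variance = 0))
  ref <- MASS::glm.nb(y ~ x, data = d)
  expect_lt(max(abs(coef(ours) - coef(ref))), 1e-3)
  expect_equal(ours$theta, ref$theta, tolerance = 0.01)
})

test_that("random-intercept fits agree with lme4 across families", {
  skip_if_not_installed("lme4")
  d <- make_poisson_glmm_data(n = 600, n_groups = 20, seed = 41)
  sp <- model_spec("y", "x", family = "poisson", random = "cohort",
                   scale_vars = character(0))
  ours <- fit_glmm(sp, d)
  ref <- lme4::glmer(y ~ x + (1 | cohort), data = d, family = poisson)
  expect_lt(max(abs(coef(ours) - lme4::fixef(ref))), 0.05)
  expect_equal(unname(ours$variance_components["cohort"]),
               unname(unlist(lme4::VarCorr(ref))), tolerance = 0.05)

  set.seed(42)
  d$w <- 2 + 0.3 * d$x + rnorm(20, 0, 0.5)[d$cohort] + rnorm(600, 0, 1.1)
  spg <- model_spec("w", "x", family = "gaussian", random = "cohort",
                    scale_vars = character(0))
  oursg <- fit_glmm(spg, d)
  refg <- lme4::lmer(w ~ x + (1 | cohort), data = d, REML = FALSE)
  expect_lt(max(abs(coef(oursg) - lme4::fixef(refg))), 1e-3)
  expect_equal(oursg$sigma2, unname(stats::sigma(refg))^2,
               tolerance = 1e-3)
})

test_that("nested female-within-cohort intercepts agree with lme4", {
  skip_if_not_installed("lme4")
  pop <- quick_population(n = 250, seed = 13)
  ann <- annual_table(pop$records, pop$calendar)
  me <- pop$sets$mast_experienced$female_id
  ann <- ann[ann$female_id %in% me, ]
  sp <- model_spec("pups", "is_mast", family = "poisson",
                   random = "female_in_cohort",
                   scale_vars = character(0))
  ours <- fit_glmm(sp, ann)
  ref <- lme4::glmer(pups ~ is_mast + (1 | cohort) + (1 | female_id),
                     data = ann, family = poisson)
  expect_lt(abs(coef(ours)["is_mast"] -
                  lme4::fixef(ref)["is_mast"]), 0.01)
  rv <- unlist(lme4::VarCorr(ref))
  expect_equal(unname(ours$variance_components["female"]),
               unname(rv["female_id"]), tolerance = 0.05)
  expect_equal(unname(ours$variance_components["cohort"]),
               unname(rv["cohort"]), tolerance = 0.05)
})

test_that("negative binomial approaches the Poisson fit as theta grows", {
  d <- make_poisson_glmm_data(n = 500, seed = 51)
  spp <- model_spec("y", "x", family = "poisson", random = "cohort",
                    scale_vars = character(0))
  spn <- model_spec("y", "x", family = "negative_binomial",
                    random = "cohort", scale_vars = character(0))
  fp <- fit_glmm(spp, d)
  fn <- fit_glmm(spn, d, glmm_control(fix_theta = 1e7))
  expect_lt(max(abs(coef(fp) - coef(fn))), 1e-3)
})

test_that("dispersion is recovered from simulated negative-binomial data", {
  set.seed(61)
  n <- 2000
  g <- rep(1:25, each = 80)
  b <- rnorm(25, 0, 0.3)
  x <- rnorm(n)
  y <- rnbinom(n, size = 10, mu = exp(1 + 0.4 * x + b[g]))
  d <- data.frame(y = y, x = x, cohort = g)
  sp <- model_spec("y", "x", family = "negative_binomial",
                   random = "cohort", scale_vars = character(0))
  f <- fit_glmm(sp, d)
  expect_lt(abs(f$theta - 10) / 10, 0.30)
})

test_that("fitting scaled predictors is equivalent to raw up to the sd factor", {
  set.seed(71)
  n <- 400
  d <- data.frame(x = rnorm(n, 10, 4), cohort = rep(1:8, each = 50))
  d$y <- rpois(n, exp(0.2 + 0.1 * d$x))
  sp_raw <- model_spec("y", "x", family = "poisson", random = "none",
                       scale_vars = character(0))
  sp_sc <- model_spec("y", "x", family = "poisson", random = "none",
                      scale_vars = "x")
  f_raw <- fit_glmm(sp_raw, d)
  f_sc <- fit_glmm(sp_sc, d)
  sdx <- stats::sd(d$x)
  expect_lt(abs(coef(f_sc)["x"] / sdx - coef(f_raw)["x"]), 1e-6)
})

test_that("adding a term never decreases the maximized log-likelihood", {
  d <- make_poisson_glmm_data(n = 300, seed = 81)
  set.seed(82)
  d$x2 <- rnorm(nrow(d))
  sp1 <- model_spec("y", "x", family = "poisson", random = "cohort",
                    scale_vars = character(0))
  sp2 <- model_spec("y", c("x", "x2"), family = "poisson",
                    random = "cohort", scale_vars = character(0))
  f1 <- fit_glmm(sp1, d)
  f2 <- fit_glmm(sp2, d)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- make_poisson_glmm_data(n = 60, seed = 91)
  d$const <- 0L
  expect_error(
    fit_glmm(model_spec("const", "x", family = "poisson",
                        random = "none", scale_vars = character(0)), d),
    "variation")
  d$g1 <- 1L
  expect_error(
    laplace_glmm(d$y, cbind(1, d$x), list(g = d$g1), "poisson"),
    "at least 2 levels")
  expect_error(model_spec("y", "x^2", family = "poisson"),
               "requires its linear term")
  expect_error(
    fit_glmm(model_spec("y", "missing_var", family = "poisson",
                        random = "none"), d),
    "missing variables")
})
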