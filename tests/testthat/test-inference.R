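test_that("a coefficient of exactly zero gives p = 1", {
  # symmetric response: OLS slope is exactly zero
  d <- data.frame(y = c(1, 2, 1), x = c(-1, 0, 1), cohort = 1:3)
  sp <- model_spec("y", "x", family = "gaussian", random = "none",
                   scale_vars = character(0))
  f <- fit_glmm(sp, d)
  row <- f$coefficients[f$coefficients$term == "x", ]
  expect_equal(row$estimate, 0, tolerance = 1e-10)
  expect_equal(row$p_value, 1, tolerance = 1e-8)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(101)
  n_rep <- 400
  pvals <- replicate(n_rep, {
    n <- 100
    d <- data.frame(x = rnorm(n), y = rpois(n, exp(0.5)), cohort = 1)
    sp <- model_spec("y", "x", family = "poisson", random = "none",
                     scale_vars = character(0))
    f <- fit_glmm(sp, d)
    f$coefficients$p_value[f$coefficients$term == "x"]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Satterthwaite df separate between- and within-group terms", {
  set.seed(111)
  n_g <- 24
  d <- data.frame(cohort = rep(1:n_g, each = 20))
  d$x <- rnorm(nrow(d))
  d$y <- 1 + 0.5 * d$x + rnorm(n_g, 0, 0.7)[d$cohort] + rnorm(nrow(d))
  sp <- model_spec("y", "x", family = "gaussian", random = "cohort",
                   scale_vars = character(0))
  f <- fit_glmm(sp, d)
  tab <- f$coefficients
  expect_identical(unique(tab$df_method), "satterthwaite")
  df_int <- tab$df[tab$term == "(Intercept)"]
  df_x <- tab$df[tab$term == "x"]
  expect_lt(df_int, 2 * n_g)          # intercept df near the group count
  expect_gt(df_x, nrow(d) / 2)        # within-group slope df near n
})

test_that("backward selection respects marginality and drops null terms", {
  set.seed(121)
  n <- 600
  d <- data.frame(x = rnorm(n), z = rnorm(n), cohort = rep(1:12, each = 50))
  d$y <- rpois(n, exp(0.3 + 0.5 * d$x))   # z and x^2 are pure noise
  sp <- model_spec("y", c("x", "x^2", "z"), family = "poisson",
                   random = "none", scale_vars = character(0))
  sel <- backward_select(sp, d)
  expect_false("z" %in% sel$spec$fixed)
  expect_false("x^2" %in% sel$spec$fixed)
  expect_true("x" %in% sel$spec$fixed)
  expect_true(all(c("z", "x^2") %in% sel$trace$dropped))
  # a quadratic keeps its linear term protected while it stays
  d2 <- data.frame(x = rnorm(n), cohort = rep(1:12, each = 50))
  d2$y <- rpois(n, exp(0.8 - 0.6 * d2$x^2))  # pure quadratic signal
  sp2 <- model_spec("y", c("x", "x^2"), family = "poisson",
                    random = "none", scale_vars = character(0))
  sel2 <- backward_select(sp2, d2)
  expect_true(all(c("x", "x^2") %in% sel2$spec$fixed))
})

test_that("a truly-zero quadratic is dropped at close to the nominal rate", {
  set.seed(131)
  n_rep <- 40
  dropped <- replicate(n_rep, {
    n <- 500
    d <- data.frame(x = rnorm(n), cohort = 1)
    d$y <- rpois(n, exp(0.4 + 0.5 * d$x))
    sp <- model_spec("y", c("x", "x^2"), family = "poisson",
                     random = "none", scale_vars = character(0))
    !"x^2" %in% backward_select(sp, d)$spec$fixed
  })
  expect_gte(mean(dropped), 0.85)   # nominal rate 1 - alpha = 0.95
})

test_that("fully significant models are left untouched", {
  d <- make_poisson_glmm_data(n = 500, beta = c(0.5, 0.9), seed = 141)
  sp <- model_spec("y", "x", family = "poisson", random = "cohort",
                   scale_vars = character(0))
  sel <- backward_select(sp, d)
  expect_identical(sel$spec$fixed, sp$fixed)
  expect_identical(nrow(sel$trace), 0L)
})

test_that("parametric bootstrap matches the analytic CI for a Gaussian GLM", {
  set.seed(151)
  n <- 150
  d <- data.frame(x = rnorm(n), cohort = 1)
  d$y <- 1 + 0.6 * d$x + rnorm(n, 0, 0.8)
  sp <- model_spec("y", "x", family = "gaussian", random = "none",
                   scale_vars = character(0))
  f <- fit_glmm(sp, d)
  bb <- bootstrap_ci(f, n_boot = 1500, seed = 7)
  wald_lo <- coef(f) - 1.96 * f$coefficients$se
  wald_hi <- coef(f) + 1.96 * f$coefficients$se
  width_b <- bb$ci$upper - bb$ci$lower
  width_w <- wald_hi - wald_lo
  expect_true(all(abs(width_b - width_w) / width_w < 0.10))
  expect_true(all(bb$ci$lower <= coef(f) & coef(f) <= bb$ci$upper))
  expect_error(bootstrap_ci(f, n_boot = 0, seed = 1), "at least 1")
  expect_error(bootstrap_ci(f, n_boot = 10), "seed")
})

test_that("bootstrap intervals cover a mixed-model coefficient", {
  d <- make_poisson_glmm_data(n = 400, n_groups = 16,
                              beta = c(0.4, 0.6), seed = 161)
  sp <- model_spec("y", "x", family = "poisson", random = "cohort",
                   scale_vars = character(0))
  f <- fit_glmm(sp, d)
  bb <- bootstrap_ci(f, n_boot = 200, seed = 3)
  row <- bb$ci[bb$ci$term == "x", ]
  expect_lt(row$lower, 0.6)
  expect_gt(row$upper, 0.6)
  b2 <- bootstrap_ci(f, n_boot = 200, seed = 3)
  expect_identical(bb$draws, b2$draws)   # seeded reproducibility
})

test_that("predicted curves apply the inverse link with delta-method SEs", {
  d <- make_poisson_glmm_data(n = 400, seed = 171)
  sp <- model_spec("y", "x", family = "poisson", random = "cohort",
                   scale_vars = character(0))
  f <- fit_glmm(sp, d)
  pc <- predict_curve(f, "x", grid = c(-1, 0, 1))
  expect_equal(pc$fit, exp(pc$eta))
  expect_equal(pc$se_fit, pc$se_eta * exp(pc$eta))
  expect_error(predict_curve(f, "nope"), "not in the model")
  expect_error(predict_curve(f, "x", at = list(bad = 1)), "unknown")
  # identity link: prediction equals the linear predictor
  set.seed(172)
  d$w <- 1 + 0.5 * d$x + rnorm(nrow(d))
  spg <- model_spec("w", "x", family = "gaussian", random = "none",
                    scale_vars = character(0))
  fg <- fit_glmm(spg, d)
  pg <- predict_curve(fg, "x", grid = c(0, 2))
  expect_equal(pg$fit, pg$eta)
})

test_that("the quadratic vertex follows -b1/(2 b2) and maps to natural units", {
  fake <- structure(list(
    engine = list(beta = c("(Intercept)" = 1, "peak_effort" = 0.454,
                           "peak_effort^2" = -0.061)),
    scaling = list(peak_effort = list(center = 3.5, scale = 2.07))
  ), class = "glmm_fit")
  v <- vertex_in_natural_units(fake, "peak_effort")
  expect_true(v$ok)
  expect_equal(v$scaled, 3.7213, tolerance = 1e-4)
  expect_equal(v$natural, 3.5 + 2.07 * v$scaled, tolerance = 1e-8)
  fake$engine$beta["peak_effort^2"] <- 0.02
  v2 <- vertex_in_natural_units(fake, "peak_effort")
  expect_false(v2$ok)
  fake$engine$beta["peak_effort"] <- 0
  fake$engine$beta["peak_effort^2"] <- -0.05
  v3 <- vertex_in_natural_units(fake, "peak_effort")
  expect_equal(v3$scaled, 0)   # optimum at the predictor mean
  expect_equal(v3$natural, 3.5)
})
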