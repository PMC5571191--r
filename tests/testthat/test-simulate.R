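test_that("identical configurations give byte-identical record tables", {
  cfg <- sim_config(n_females = 120, seed = 31)
  r1 <- simulate_population(cfg)
  r2 <- simulate_population(sim_config(n_females = 120, seed = 31))
  attr(r1, "config") <- attr(r2, "config") <- NULL
  expect_identical(r1, r2)
})

test_that("recruits never exceed pups and ages are within lifespan", {
  rec <- simulate_population(sim_config(n_females = 400, seed = 5))
  expect_true(all(rec$recruits <= rec$pups))
  expect_true(all(rec$recruits >= 0))
  expect_true(all(rec$age >= 1))
  expect_identical(rec$year, rec$cohort + rec$age)
  # one row per female-year of life: ages are 1..lifespan with no gaps
  by_f <- split(rec$age, rec$female_id)
  expect_true(all(vapply(by_f, function(a) identical(sort(a),
                                                     seq_len(max(a))),
                         TRUE)))
})

test_that("pooled recruitment proportions match the configured rates", {
  cfg <- sim_config(n_females = 5000, seed = 17,
                    recruit_prob_nonmast = 0.20, recruit_prob_mast = 0.41)
  rec <- simulate_population(cfg)
  mast <- rec$year %in% cfg$calendar$mast_years
  p_non <- sum(rec$recruits[!mast]) / sum(rec$pups[!mast])
  p_mast <- sum(rec$recruits[mast]) / sum(rec$pups[mast])
  expect_lt(abs(p_non - 0.20), 0.02)
  expect_lt(abs(p_mast - 0.41), 0.02)
})

test_that("annual pup means among breeders approach the calibration targets", {
  # cohort intercepts are only 24 draws, so silence that noise source and
  # test the structural calibration
  cfg <- sim_config(n_females = 5000, seed = 23, cohort_variance = 0)
  rec <- simulate_population(cfg)
  cal <- cfg$calendar
  s <- summarize_females(rec, cal)
  br <- rec[rec$female_id %in% s$female_id[s$breeder], ]
  mast <- br$year %in% cal$mast_years
  expect_lt(abs(mean(br$pups[!mast]) - 2.08), 0.15)
  expect_lt(abs(mean(br$pups[mast]) - 3.66), 0.25)
  # lifespans tuned for roughly 3 breeding events (median) among
  # mast-experienced females, peaks spanning ages 1-7
  me <- s[s$breeder & s$experienced_mast, ]
  expect_equal(stats::median(me$n_breeding_years), 3)
  pk <- s$peak_age[s$breeder]
  expect_identical(min(pk), 1L)
  expect_gte(max(pk), 5)
  expect_equal(stats::median(pk), 2)
})

test_that("without mast effect or heterogeneity, mast and non-mast pups are exchangeable", {
  cfg <- sim_config(n_females = 3000, seed = 41, mast_litter_effect = 0,
                    cohort_variance = 0, female_variance = 0,
                    base_log_litter_mean = log(2.2))
  rec <- simulate_population(cfg)
  rec$is_mast <- as.integer(rec$year %in% cfg$calendar$mast_years)
  rec <- rec[rec$pups > 0 | ave(rec$pups, rec$female_id, FUN = max) > 0, ]
  sp <- model_spec("pups", "is_mast", family = "poisson",
                   random = "none", scale_vars = character(0))
  f <- fit_glmm(sp, rec)
  est <- f$coefficients[f$coefficients$term == "is_mast", ]
  expect_lt(abs(est$estimate), 3 * est$se)
})

test_that("zero-fertility configuration yields an empty analysis set", {
  cfg <- sim_config(n_females = 50, seed = 3,
                    base_log_litter_mean = -Inf)
  rec <- simulate_population(cfg)
  expect_true(all(rec$pups == 0))
  s <- summarize_females(rec, cfg$calendar)
  expect_identical(nrow(build_analysis_sets(s)$full), 0L)
})

test_that("record tables round-trip through CSV", {
  rec <- simulate_population(sim_config(n_females = 60, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  attr(rec, "config") <- NULL
  expect_identical(back, rec)
  expect_identical(nrow(back), nrow(rec))
  expect_error(write_records(rec[0, ], path), "non-empty")
})

test_that("simulation configs validate and load from YAML", {
  expect_error(sim_config(recruit_prob_mast = 1.2), "probabilities")
  expect_error(sim_config(cohort_variance = -1), "non-negative")
  expect_error(sim_config(n_females = 0), "n_females")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_females: 40", "seed: 12", "calendar_start: 1986",
               "calendar_end: 2013",
               "mast_years: [1993, 1998, 2005, 2010]",
               "recruit_prob_mast: 0.35"), path)
  cfg <- sim_config_from_yaml(path)
  expect_identical(cfg$n_females, 40L)
  expect_identical(cfg$seed, 12L)
  expect_equal(cfg$recruit_prob_mast, 0.35)
  cfg2 <- sim_config_from_yaml(path, seed = 99)
  expect_identical(cfg2$seed, 99L)
  writeLines("not_a_field: 1", path)
  expect_error(sim_config_from_yaml(path), "unknown config keys")
})
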