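# Shared fixture builders: everything is generated in code at test time.

test_calendar <- function() default_calendar()

# Hand-built annual records for one or more females.  `pups` is a list of
# per-age pup counts; recruits default to zero.
make_records <- function(pups, cohort = 2000, recruits = NULL,
                         ids = NULL) {
  if (!is.list(pups)) pups <- list(pups)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_along(pups))
  if (length(cohort) == 1L) cohort <- rep(cohort, length(pups))
  parts <- lapply(seq_along(pups), function(i) {
    p <- pups[[i]]
    r <- if (is.null(recruits)) rep(0L, length(p)) else recruits[[i]]
    data.frame(female_id = ids[i], cohort = cohort[i],
               year = cohort[i] + seq_along(p), age = seq_along(p),
               pups = as.integer(p), recruits = as.integer(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

# Small simulated population with summaries and analysis sets.
quick_population <- function(n = 300, seed = 1, ...) {
  cfg <- sim_config(n_females = n, seed = seed, ...)
  rec <- simulate_population(cfg)
  cal <- cfg$calendar
  s <- summarize_females(rec, cal)
  sets <- build_analysis_sets(s)
  list(cfg = cfg, records = rec, calendar = cal, summaries = s,
       sets = sets)
}

# Poisson test data with a cohort random intercept, for engine checks.
make_poisson_glmm_data <- function(n = 400, n_groups = 20, beta = c(0.5, 0.8),
                                   group_sd = 0.4, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), length.out = n))
  b <- rnorm(n_groups, 0, group_sd)
  x <- rnorm(n)
  y <- rpois(n, exp(beta[1] + beta[2] * x + b[g]))
  data.frame(y = y, x = x, cohort = g, female_id = seq_len(n))
}
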