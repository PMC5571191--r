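analysis_names <- c("lifetime_pups", "lifetime_recruits",
                    "peak_year_timing", "annual_pups_mast",
                    "annual_recruits_mast", "mast_peak_fitness",
                    "mast_constraint", "post_peak_survival",
                    "post_peak_reproduction")

#' Default model specifications for the full analysis
#'
#' One [model_spec()] per analysis: Poisson GLMM for lifetime pups,
#' negative-binomial GLMM for lifetime recruits (both with linear +
#' quadratic peak effort and peak age, lifespan and primiparity, cohort
#' random intercept); binomial GLMM for whether a year is the peak year,
#' Poisson / negative-binomial GLMMs for annual pups and recruits against
#' the mast flag (female-within-cohort random intercepts); the mast-peak
#' fitness model; the age-at-mast constraint model; and the post-peak
#' lifespan (Gaussian LMM) and post-peak reproduction (Poisson GLMM)
#' cost models.  Binary covariates are coded 0/1 with delayed primiparity
#' and non-mast as reference levels.
#'
#' @return Named list of `model_spec` objects.
#' @export
default_model_specs <- function() {
  lifetime_terms <- c("peak_effort", "peak_effort^2", "peak_age",
                      "peak_age^2", "lifespan", "primiparity")
  cost_terms <- c("mast_peak", "peak_effort", "mast_peak:peak_effort",
                  "peak_age")
  list(
    lifetime_pups = model_spec("lifetime_pups", lifetime_terms,
                               family = "poisson", random = "cohort"),
    lifetime_recruits = model_spec("lifetime_recruits", lifetime_terms,
                                   family = "negative_binomial",
                                   random = "cohort"),
    peak_year_timing = model_spec("is_peak_year", "is_mast",
                                  family = "binomial",
                                  random = "female_in_cohort"),
    annual_pups_mast = model_spec("pups", "is_mast", family = "poisson",
                                  random = "female_in_cohort"),
    annual_recruits_mast = model_spec("recruits", "is_mast",
                                      family = "negative_binomial",
                                      random = "female_in_cohort"),
    mast_peak_fitness = model_spec("lifetime_recruits",
                                   c("mast_peak", "lifespan",
                                     "primiparity"),
                                   family = "negative_binomial",
                                   random = "cohort"),
    mast_constraint = model_spec("mast_peak",
                                 c("age_at_mast", "age_at_mast^2",
                                   "pre_peak_rate"),
                                 family = "binomial", random = "cohort"),
    post_peak_survival = model_spec("post_peak_lifespan", cost_terms,
                                    family = "gaussian",
                                    random = "cohort"),
    post_peak_reproduction = model_spec("post_peak_pups", cost_terms,
                                        family = "poisson",
                                        random = "cohort")
  )
}

prepare_model_frame <- function(df) {
  for (v in c("experienced_mast", "mast_peak", "breeder")) {
    if (v %in% names(df)) df[[v]] <- as.integer(df[[v]])
  }
  df
}

#' Run the full peak-effort analysis
#'
#' Orchestrates the whole pipeline on a records table: derives the annual
#' table and per-female summaries, builds the analysis subsets, fits every
#' configured mixed model (with backward selection), computes the
#' quadratic optima of peak effort, the group descriptive statistics and
#' the constrained-resampling null test for the peak-effort slope.
#'
#' Lifetime models use all breeders with a cohort random intercept; the
#' annual (peak-year timing, annual pups, annual recruits) models use the
#' annual records of mast-experienced females with female-within-cohort
#' random intercepts; the mast-peak fitness, constraint and post-peak cost
#' models use the mast-experienced breeders.
#'
#' @param records Annual-record `data.frame` (see [read_records()]).
#' @param calendar A [make_mast_calendar()] covering all record years.
#' @param config Named list of options: `select` (backward selection,
#'   default `TRUE`), `alpha` (0.05), `models` (subset of analysis names
#'   to run), `null_test` (default `TRUE`), `null_iterations` (1000),
#'   `seed` (1), `control` (a [glmm_control()]).
#' @return Object of class `analysis_report`: list with `models` (per
#'   analysis: `fit`, `initial_fit`, `trace`, `spec`), `vertices`,
#'   `descriptives`, `null_test`, `sets` (row counts), `summaries`,
#'   `annual`, `provenance`.
#' @export
run_full_analysis <- function(records, calendar, config = list()) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records table is empty")
  }
  stopifnot(inherits(calendar, "mast_calendar"))
  if (!all(records$year %in% calendar$years)) {
    stop("calendar does not cover all record years")
  }
  cfg <- utils::modifyList(
    list(select = TRUE, alpha = 0.05, models = analysis_names,
         null_test = TRUE, null_iterations = 1000L, seed = 1L,
         control = glmm_control()),
    config)
  specs <- default_model_specs()[intersect(analysis_names, cfg$models)]

  annual <- annual_table(records, calendar)
  summaries <- summarize_females(records, calendar)
  sets <- build_analysis_sets(summaries)
  if (nrow(sets$full) == 0L) {
    stop("empty analysis set: no breeders (filter 'full')")
  }

  full_df <- prepare_model_frame(sets$full)
  mast_df <- prepare_model_frame(sets$mast_experienced)
  annual_mast <- annual[annual$female_id %in% mast_df$female_id, ,
                        drop = FALSE]
  data_for <- function(name) {
    switch(name,
      lifetime_pups = , lifetime_recruits = full_df,
      peak_year_timing = , annual_pups_mast = ,
      annual_recruits_mast = annual_mast,
      mast_peak_fitness = , mast_constraint = ,
      post_peak_survival = , post_peak_reproduction = mast_df)
  }

  models <- list()
  for (name in names(specs)) {
    dat <- data_for(name)
    if (nrow(dat) == 0L) {
      stop("empty analysis set for model '", name,
           "' (filter 'mast_experienced')")
    }
    init <- fit_glmm(specs[[name]], dat, cfg$control)
    if (cfg$select) {
      sel <- backward_select(specs[[name]], dat, cfg$alpha, cfg$control)
      models[[name]] <- list(fit = sel$fit, initial_fit = init,
                             trace = sel$trace, spec = sel$spec)
    } else {
      models[[name]] <- list(fit = init, initial_fit = init,
                             trace = NULL, spec = specs[[name]])
    }
  }

  vertices <- list()
  for (nm in c(pups = "lifetime_pups", recruits = "lifetime_recruits")) {
    if (!nm %in% names(models)) next
    fit <- models[[nm]]$fit
    key <- paste0("vertex_", sub("lifetime_", "", nm))
    vertices[[key]] <-
      if (all(c("peak_effort", "peak_effort^2") %in%
              names(fit$engine$beta))) {
        vertex_in_natural_units(fit, "peak_effort")
      } else {
        list(ok = FALSE, reason = "quadratic peak-effort term not retained")
      }
  }

  descriptives <- group_descriptives(annual_mast, mast_df)

  null_test <- NULL
  if (isTRUE(cfg$null_test) && "lifetime_pups" %in% names(models)) {
    sp <- models[["lifetime_pups"]]$spec
    if ("peak_effort" %in% sp$fixed) {
      null_test <- null_slope_distribution(
        full_df, sp, n_iterations = cfg$null_iterations, seed = cfg$seed,
        term = "peak_effort", control = cfg$control)
    } else {
      null_test <- list(skipped = "peak_effort not retained in best model")
    }
  }

  structure(list(
    models = models,
    vertices = vertices,
    descriptives = descriptives,
    null_test = null_test,
    sets = vapply(sets, nrow, 1L),
    summaries = summaries,
    annual = annual,
    provenance = list(
      n_records = nrow(records),
      n_females = length(unique(records$female_id)),
      checksum = sum(records$pups) + 31 * sum(records$recruits) +
        7 * sum(records$year),
      seed = cfg$seed,
      config = cfg[c("select", "alpha", "models", "null_test",
                     "null_iterations")]
    )
  ), class = "analysis_report")
}

#' Group descriptive statistics
#'
#' Arithmetic means, standard deviations and counts of the quantities the
#' study summarizes by group: annual pups and recruits by mast status,
#' lifetime recruits, percent of pups recruited and post-peak lifespan by
#' mast-peak status.  A group of one reports a missing sd.
#'
#' @param annual Annual table (typically the mast-experienced subset) from
#'   [annual_table()].
#' @param summaries Matching per-female summaries.
#' @return Data frame with columns `variable`, `group`, `mean`, `sd`, `n`.
#' @export
group_descriptives <- function(annual, summaries) {
  grp <- function(x, g, labels, variable) {
    parts <- lapply(unique(g), function(lev) {
      xi <- x[g == lev & !is.na(x)]
      data.frame(variable = variable,
                 group = labels[as.character(lev)],
                 mean = if (length(xi)) mean(xi) else NA_real_,
                 sd = if (length(xi) > 1) stats::sd(xi) else NA_real_,
                 n = length(xi), stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  empty <- data.frame(variable = character(0), group = character(0),
                      mean = numeric(0), sd = numeric(0), n = integer(0))
  if (nrow(annual) == 0L || nrow(summaries) == 0L) return(empty)
  mast_lab <- c("0" = "non-mast", "1" = "mast")
  peak_lab <- c("0" = "non-mast peak", "1" = "mast peak")
  out <- rbind(
    grp(annual$pups, annual$is_mast, mast_lab, "annual_pups"),
    grp(annual$recruits, annual$is_mast, mast_lab, "annual_recruits"),
    grp(summaries$lifetime_recruits, as.integer(summaries$mast_peak),
        peak_lab, "lifetime_recruits"),
    grp(100 * summaries$prop_recruited, as.integer(summaries$mast_peak),
        peak_lab, "pct_recruited"),
    grp(summaries$post_peak_lifespan, as.integer(summaries$mast_peak),
        peak_lab, "post_peak_lifespan")
  )
  rownames(out) <- NULL
  out[order(out$variable, out$group), ]
}

#' Sensitivity reruns on restricted subsets
#'
#' Repeats the analysis after excluding single-year breeders
#' (`"multi_year"`), or restricted to females that never experienced a
#' mast year (`"never_mast"`; only the lifetime models apply there, since
#' the mast-experienced subset is empty by construction).
#'
#' @param records Annual-record table.
#' @param calendar A `mast_calendar`.
#' @param subset `"multi_year"` or `"never_mast"`.
#' @param config Options forwarded to [run_full_analysis()].
#' @return An `analysis_report` for the restricted data.
#' @export
sensitivity_reruns <- function(records, calendar,
                               subset = c("multi_year", "never_mast"),
                               config = list()) {
  subset <- match.arg(subset)
  summaries <- summarize_females(records, calendar)
  sets <- build_analysis_sets(summaries)
  ids <- sets[[subset]]$female_id
  if (!length(ids)) stop("empty analysis set: filter '", subset, "'")
  sub_rec <- records[records$female_id %in% ids, , drop = FALSE]
  if (subset == "never_mast") {
    config$models <- intersect(config$models %||%
                                 c("lifetime_pups", "lifetime_recruits"),
                               c("lifetime_pups", "lifetime_recruits"))
  }
  run_full_analysis(sub_rec, calendar, config)
}

#' Write per-model coefficient tables
#'
#' One CSV per fitted model with columns term, estimate, CI bounds (when
#' bootstrap intervals were computed), statistic and p, mirroring the
#' layout of published mixed-model result tables.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report_tables <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (name in names(report$models)) {
    tab <- report$models[[name]]$fit$coefficients
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(report$null_test) &&
      inherits(report$null_test, "null_distribution")) {
    path <- file.path(dir, "null_test.csv")
    report_null_test(report$null_test, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Peak-effort analysis report\n")
  cat(sprintf("  %d records, %d females; sets: %s\n",
              x$provenance$n_records, x$provenance$n_females,
              paste(sprintf("%s=%d", names(x$sets), x$sets),
                    collapse = ", ")))
  for (name in names(x$models)) {
    fit <- x$models[[name]]$fit
    cat(sprintf("  [%s] %s, %d terms, logLik %.2f%s\n", name,
                fit$spec$family, nrow(fit$coefficients), fit$loglik,
                if (fit$converged) "" else " (not converged)"))
  }
  for (key in names(x$vertices)) {
    v <- x$vertices[[key]]
    if (isTRUE(v$ok)) {
      cat(sprintf("  %s: optimum peak effort %.2f pups\n", key, v$natural))
    }
  }
  if (inherits(x$null_test, "null_distribution")) print(x$null_test)
  invisible(x)
}
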