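#' Summarize one female's annual records
#'
#' Derives the per-female life-history variables used throughout the
#' analyses: peak effort (maximum annual pups), peak age (age at which that
#' maximum is *first* achieved), lifetime totals, primiparity (yearling vs
#' delayed first litter), mast exposure and mast-peak indicators, pre-peak
#' reproductive rate and the post-peak metrics.
#'
#' Records are re-sorted by year, so the summary is invariant to row
#' permutation.  A female whose records carry zero pups throughout is
#' flagged `breeder = FALSE` and excluded from the analysis sets by
#' [build_analysis_sets()].
#'
#' @param records Annual records of a single female (`data.frame` with
#'   columns `female_id, cohort, year, age, pups, recruits`; `age` may be
#'   omitted and is then derived as `year - cohort`).
#' @param calendar A [make_mast_calendar()] object.
#' @return One-row `data.frame`; see Details for columns.
#'
#' @details Columns of the summary:
#' \describe{
#'   \item{lifespan}{maximum recorded age (records span ages 1..lifespan)}
#'   \item{peak_effort, peak_age}{maximum annual pups and first age
#'     achieving it}
#'   \item{lifetime_pups, lifetime_recruits, prop_recruited}{lifetime
#'     totals and their ratio}
#'   \item{primiparity}{1 if the first year with pups > 0 is age 1,
#'     0 otherwise (delayed; reference level)}
#'   \item{n_breeding_years}{number of years with pups > 0}
#'   \item{experienced_mast}{any mast year at adult age (>= 1) within the
#'     lifespan}
#'   \item{mast_peak}{the peak year (first attainment) is a mast year}
#'   \item{age_at_mast}{age in the first adult mast year, `NA` if none}
#'   \item{pre_peak_rate}{pups per year before the peak age
#'     (0 when peak_age = 1)}
#'   \item{post_peak_lifespan, post_peak_pups}{years lived and pups
#'     produced after the peak age}
#' }
#' @export
summarize_female <- function(records, calendar) {
  stopifnot(inherits(calendar, "mast_calendar"))
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must contain at least one row")
  }
  if (length(unique(records$female_id)) != 1L) {
    stop("summarize_female expects records of a single female")
  }
  if (!"age" %in% names(records)) {
    records$age <- records$year - records$cohort
  }
  if (anyDuplicated(records$year)) stop("duplicate years for a female")
  if (any(records$recruits > records$pups)) stop("recruits exceed pups")
  if (any(records$age < 1L)) stop("breeding records require age >= 1")
  records <- records[order(records$year), , drop = FALSE]

  cohort <- records$cohort[1]
  lifespan <- max(records$age)
  pups <- records$pups
  ages <- records$age
  lifetime_pups <- sum(pups)
  lifetime_recruits <- sum(records$recruits)
  breeder <- lifetime_pups > 0L

  mast_ages <- ages[is_mast_year(calendar, records$year)]
  experienced_mast <- length(mast_ages) > 0L
  age_at_mast <- if (experienced_mast) min(mast_ages) else NA_integer_

  if (breeder) {
    peak_effort <- max(pups)
    peak_idx <- which(pups == peak_effort)[1]
    peak_age <- ages[peak_idx]
    peak_year <- records$year[peak_idx]
    mast_peak <- is_mast_year(calendar, peak_year)
    first_breed_age <- min(ages[pups > 0L])
    primiparity <- as.integer(first_breed_age == 1L)
    pre <- ages < peak_age
    pre_peak_rate <- if (peak_age > 1L) sum(pups[pre]) / (peak_age - 1) else 0
    post <- ages > peak_age
    post_peak_lifespan <- lifespan - peak_age
    post_peak_pups <- sum(pups[post])
    prop_recruited <- lifetime_recruits / lifetime_pups
  } else {
    peak_effort <- 0L; peak_age <- NA_integer_; mast_peak <- NA
    primiparity <- NA_integer_; pre_peak_rate <- NA_real_
    post_peak_lifespan <- NA_integer_; post_peak_pups <- NA_integer_
    prop_recruited <- NA_real_
  }

  data.frame(
    female_id = records$female_id[1],
    cohort = cohort,
    lifespan = lifespan,
    breeder = breeder,
    peak_effort = peak_effort,
    peak_age = peak_age,
    lifetime_pups = lifetime_pups,
    lifetime_recruits = lifetime_recruits,
    prop_recruited = prop_recruited,
    primiparity = primiparity,
    n_breeding_years = sum(pups > 0L),
    experienced_mast = experienced_mast,
    mast_peak = mast_peak,
    age_at_mast = age_at_mast,
    pre_peak_rate = pre_peak_rate,
    post_peak_lifespan = post_peak_lifespan,
    post_peak_pups = post_peak_pups,
    stringsAsFactors = FALSE
  )
}

#' Summarize all females in a records table
#'
#' @param records Annual-record `data.frame` (multiple females).
#' @param calendar A [make_mast_calendar()] object.
#' @return `data.frame` with one row per female (see [summarize_female()]).
#' @export
summarize_females <- function(records, calendar) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must contain at least one row")
  }
  parts <- lapply(split(records, records$female_id),
                  summarize_female, calendar = calendar)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Build the analysis subsets
#'
#' Partitions the per-female summaries into the subsets used by the
#' analyses: all breeders (`full`), breeders that experienced at least one
#' adult mast year (`mast_experienced`), the complementary never-mast
#' breeders (`never_mast`), and breeders with more than one breeding year
#' (`multi_year`, the sensitivity set that drops single-year breeders).
#'
#' @param summaries Output of [summarize_females()].
#' @return Named list of `data.frame`s:
#'   `full`, `mast_experienced`, `never_mast`, `multi_year`.
#' @export
build_analysis_sets <- function(summaries) {
  full <- summaries[summaries$breeder, , drop = FALSE]
  list(
    full = full,
    mast_experienced = full[full$experienced_mast, , drop = FALSE],
    never_mast = full[!full$experienced_mast, , drop = FALSE],
    multi_year = full[full$n_breeding_years > 1L, , drop = FALSE]
  )
}

#' Annual table with mast and peak-year status
#'
#' Augments the records with `age` (if absent), the `is_mast` flag and the
#' binary `is_peak_year` status: 1 in every year in which the female's
#' annual pups equal her lifetime maximum (ties flag all attaining years,
#' while peak age takes the first), 0 otherwise.  Non-breeders carry
#' `is_peak_year = 0` throughout.
#'
#' @param records Annual-record `data.frame`.
#' @param calendar A [make_mast_calendar()] object.
#' @return The records with columns `is_mast` (0/1) and `is_peak_year`
#'   (0/1) appended, sorted by female and year.
#' @export
annual_table <- function(records, calendar) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must contain at least one row")
  }
  if (!"age" %in% names(records)) {
    records$age <- records$year - records$cohort
  }
  records <- records[order(records$female_id, records$year), , drop = FALSE]
  records$is_mast <- as.integer(is_mast_year(calendar, records$year))
  peak <- stats::ave(records$pups, records$female_id, FUN = max)
  records$is_peak_year <- as.integer(records$pups == peak & peak > 0L)
  rownames(records) <- NULL
  records
}

#' Center and scale a predictor
#'
#' Standardizes to mean zero and unit sample standard deviation (divisor
#' n - 1), returning the scaling constants needed to convert model
#' coefficients and optima back to natural units.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return List with `scaled`, `center` (mean) and `scale` (sd).
#' @examples
#' scale_predictors(c(1, 2, 3))$scaled  # -1 0 1
#' @export
scale_predictors <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("cannot scale a predictor with missing values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot scale a constant predictor")
  }
  m <- mean(values)
  list(scaled = (values - m) / s, center = m, scale = s)
}

#' Invert predictor scaling
#'
#' @param scaled Scaled values.
#' @param info List with `center` and `scale` (as from
#'   [scale_predictors()]).
#' @return Values on the natural scale.
#' @export
unscale_predictors <- function(scaled, info) {
  info$center + info$scale * scaled
}
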