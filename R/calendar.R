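#' Construct a mast calendar
#'
#' A mast calendar is the set of consecutive study years together with the
#' subset of years in which the masting tree species (white spruce in the
#' motivating system) produced a synchronized superabundant seed crop.
#' Mast years drive juvenile overwinter survival and are the resource pulse
#' around which the peak-effort analyses revolve.
#'
#' @param start_year First calendar year of the study window.
#' @param end_year Last calendar year of the study window (inclusive).
#' @param mast_years Integer vector of mast years; must lie within
#'   `[start_year, end_year]` and must not cover every year.
#'
#' @return An object of class `mast_calendar`: a list with `years`
#'   (increasing integer vector) and `mast_years` (integer vector).
#'
#' @examples
#' cal <- make_mast_calendar(1986, 2013, c(1993, 1998, 2005, 2010))
#' length(cal$years)       # 28
#' is_mast_year(cal, 1998) # TRUE
#' @export
make_mast_calendar <- function(start_year, end_year, mast_years = integer()) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  mast_years <- sort(unique(as.integer(mast_years)))
  if (length(start_year) != 1L || length(end_year) != 1L ||
      is.na(start_year) || is.na(end_year)) {
    stop("start_year and end_year must be single non-missing years")
  }
  if (start_year > end_year) {
    stop("start_year must not exceed end_year")
  }
  years <- start_year:end_year
  if (length(mast_years) && !all(mast_years %in% years)) {
    bad <- setdiff(mast_years, years)
    stop("mast years outside study window: ", paste(bad, collapse = ", "))
  }
  if (length(mast_years) >= length(years)) {
    stop("calendar must contain at least one non-mast year")
  }
  structure(list(years = years, mast_years = mast_years),
            class = "mast_calendar")
}

#' Is a year a mast year?
#'
#' @param calendar A [make_mast_calendar()] object.
#' @param year Integer vector of calendar years.
#' @return Logical vector, `TRUE` where `year` is a mast year.
#' @export
is_mast_year <- function(calendar, year) {
  stopifnot(inherits(calendar, "mast_calendar"))
  as.integer(year) %in% calendar$mast_years
}

#' Default study calendar
#'
#' The 1986--2013 window with mast years 1993, 1998, 2005 and 2010, the
#' configuration of the motivating red-squirrel study population.
#'
#' @return A `mast_calendar`.
#' @export
default_calendar <- function() {
  make_mast_calendar(1986, 2013, c(1993L, 1998L, 2005L, 2010L))
}

#' @export
print.mast_calendar <- function(x, ...) {
  cat("Mast calendar:", min(x$years), "-", max(x$years),
      sprintf("(%d years, %d mast: %s)\n", length(x$years),
              length(x$mast_years), paste(x$mast_years, collapse = ", ")))
  invisible(x)
}
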