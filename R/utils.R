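#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: 0.05 rounds to 0.1,
#' -0.05 to -0.1. Base [round()] rounds half to even, which disagrees with
#' printed epidemiological tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(87.55, 7.65, -0.05))
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# percentage of count over total, printed precision
pct1 <- function(count, total) round_half_up(100 * count / total, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_cfg(field, "must be a proportion in [0, 1]")
  x
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# split a ";"-collapsed set string back into a character vector
split_set <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
}

collapse_set <- function(x) paste(sort(unique(x)), collapse = ";")

# TRUE where set string `a` contains an element absent from set string `b`
set_has_new <- function(a, b) {
  mapply(function(x, y) length(setdiff(split_set(x), split_set(y))) > 0, a, b,
         USE.NAMES = FALSE)
}

#' Anniversary dates of an index date
#'
#' Calendar anniversaries of the index date for years 0..`n_years`; a
#' February 29 index maps to February 28 in non-leap years. Consecutive
#' anniversaries are therefore 365 or 366 days apart.
#'
#' @param index_date a `Date` (or string coercible to one).
#' @param n_years number of follow-up years (default 5).
#' @return vector of `n_years + 1` dates, the first being the index date.
#' @export
#' @examples
#' anniversary_dates(as.Date("2016-09-01"))
#' anniversary_dates(as.Date("2016-02-29"), 1)  # -> 2017-02-28
anniversary_dates <- function(index_date, n_years = 5) {
  index_date <- as_date(index_date)
  stopifnot(length(index_date) == 1, !is.na(index_date))
  y <- as.integer(format(index_date, "%Y"))
  md <- format(index_date, "%m-%d")
  out <- vapply(0:n_years, function(k) {
    target <- paste0(y + k, "-", md)
    d <- as.Date(target, format = "%Y-%m-%d")
    if (is.na(d)) d <- as.Date(paste0(y + k, "-02-28"))  # Feb 29 in non-leap year
    as.numeric(d)
  }, numeric(1))
  as.Date(out, origin = "1970-01-01")
}

# vectorized calendar-anniversary shift by k years (Feb 29 -> Feb 28)
ann_shift <- function(dates, k) {
  dates <- as_date(dates)
  y <- as.integer(format(dates, "%Y")) + k
  md <- format(dates, "%m-%d")
  d <- as.Date(paste0(y, "-", md), format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(dates)
  if (any(bad)) d[bad] <- as.Date(paste0(y[bad], "-02-28"))
  d
}

# index date minus k calendar years (same leap rule as anniversaries)
years_before <- function(date, k) {
  date <- as_date(date)
  y <- as.integer(format(date, "%Y"))
  md <- format(date, "%m-%d")
  d <- as.Date(paste0(y - k, "-", md), format = "%Y-%m-%d")
  if (is.na(d)) d <- as.Date(paste0(y - k, "-02-28"))
  d
}

# completed years at `date` for a birth year, July-1 birthday convention
# (the source database stores year of birth only)
age_at <- function(date, birth_year) {
  date <- as_date(date)
  as.integer(format(date, "%Y")) - birth_year -
    as.integer(format(date, "%m-%d") < "07-01")
}

age_band_of <- function(age) {
  cut(age, breaks = c(-Inf, 49, 64, 74, Inf),
      labels = c("35-49", "50-64", "65-74", ">=75"))
}
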