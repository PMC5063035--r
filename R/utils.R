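#' Shift a date by whole calendar months, clamped to month end
#'
#' "12 months after" a date means the same day-of-month one year later; when
#' that day does not exist (for example 29 February in a non-leap year) the
#' result is clamped to the last day of the target month. All lookback and
#' follow-up windows in the package use this rule, so a 12-month follow-up
#' window is exactly `[entry, add_months(entry, 12))`.
#'
#' @param date a `Date` vector.
#' @param n integer number of months; negative values shift backwards.
#' @return a `Date` vector of the same length.
#' @examples
#' add_months(as.Date("2013-01-31"), 1)   # 2013-02-28
#' add_months(as.Date("2013-03-15"), -12) # 2012-03-15
#' @export
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  lubridate::add_with_rollback(date, months(as.integer(n)), roll_to_first = FALSE)
}

#' Round half away from zero
#'
#' Report tables round percentages half-up to one decimal (so 26.95 prints as
#' 27.0), unlike base [round()] which rounds half to even. A small epsilon
#' guards against binary representation of exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / scale
}

#' Percentage of a count, rounded for report tables
#'
#' @param count numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 1, the report convention).
#' @return percentage(s) on the 0-100 scale, rounded half-up.
#' @examples
#' percent_of(10776, 39743) # 27.1
#' @export
percent_of <- function(count, total, digits = 1) {
  if (total <= 0) {
    return(rep(NA_real_, length(count)))
  }
  round_half_up(100 * count / total, digits)
}

#' Age in completed years at a reference date
#'
#' Standard epidemiological convention: the number of whole birthdays elapsed.
#'
#' @param birth_date,at_date `Date` vectors (recycled to common length).
#' @return integer vector of ages.
#' @export
age_at <- function(birth_date, at_date) {
  stopifnot(inherits(birth_date, "Date"), inherits(at_date, "Date"))
  age <- year(at_date) - year(birth_date)
  before_birthday <- (month(at_date) < month(birth_date)) |
    (month(at_date) == month(birth_date) & day(at_date) < day(birth_date))
  as.integer(age - before_birthday)
}

# internal: civil calendar quarter (Jan-Mar = 1, ..., Oct-Dec = 4) as a
# year*4+quarter integer so distinct values = distinct calendar quarters
quarter_index <- function(date) {
  year(date) * 4L + (month(date) - 1L) %/% 3L
}
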