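#' @importFrom rlang .data
#' @importFrom stats rbinom rnorm runif setNames qlnorm plnorm
NULL

#' Normalise a month specification to the first day of the month
#'
#' Accepts `Date`s, `"YYYY-MM"` or `"YYYY-MM-DD"` strings and returns the
#' `Date` of day 1 of that calendar month. Months are represented this way
#' throughout the package.
#'
#' @param x a `Date` vector or character vector.
#' @return a `Date` vector, day-of-month 1.
#' @export
as_month <- function(x) {
  if (is.character(x)) {
    x <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
    x <- as.Date(x)
  }
  if (!inherits(x, "Date")) stop("month must be a Date or 'YYYY-MM' string", call. = FALSE)
  as.Date(format(x, "%Y-%m-01"))
}

#' First and last day of a month
#' @param month anything accepted by [as_month()].
#' @return a `Date` vector.
#' @export
month_start <- function(month) as_month(month)

#' @rdname month_start
#' @export
month_end <- function(month) {
  m <- as_month(month)
  add_months(m, 1L) - 1L
}

#' Shift a first-of-month date by whole calendar months
#' @param month a `Date` on day 1.
#' @param n integer number of months (vectorised).
#' @return a `Date` vector on day 1.
#' @export
add_months <- function(month, n) {
  m <- as_month(month)
  y <- as.integer(format(m, "%Y"))
  mo <- as.integer(format(m, "%m")) - 1L + as.integer(n)
  as.Date(sprintf("%04d-%02d-01", y + mo %/% 12L, mo %% 12L + 1L))
}

#' Sequence of study months
#' @param from,to month specifications (see [as_month()]); `from <= to`.
#' @return `Date` vector of consecutive month starts.
#' @export
month_seq <- function(from, to) {
  from <- as_month(from); to <- as_month(to)
  if (from > to) stop("study window start must not be after its end", call. = FALSE)
  seq(from, to, by = "1 month")
}

#' Age in whole years at a reference date
#' @param birth_date,on `Date` vectors.
#' @return integer years (floored).
#' @export
age_years <- function(birth_date, on) {
  by <- as.integer(format(birth_date, "%Y")); bm <- as.integer(format(birth_date, "%m"))
  bd <- as.integer(format(birth_date, "%d"))
  oy <- as.integer(format(on, "%Y")); om <- as.integer(format(on, "%m"))
  od <- as.integer(format(on, "%d"))
  oy - by - as.integer(om < bm | (om == bm & od < bd))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, in contrast to base R's round-half-even.
#' Report percentages use one decimal place so that e.g. 3.7706 prints as 3.8.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
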