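#' Warm/cold season specification
#'
#' The seasonal partition used throughout: warm = May-October, cold =
#' November-April. The two month sets must partition the 12 calendar months.
#'
#' @param warm_months,cold_months Integer month numbers.
#' @return An object of class `oz_seasons`.
#' @export
season_spec <- function(warm_months = 5:10, cold_months = c(11:12, 1:4)) {
  if (!setequal(c(warm_months, cold_months), 1:12) ||
      length(intersect(warm_months, cold_months)) > 0) {
    abort("warm and cold months must partition the 12 calendar months")
  }
  structure(list(warm = sort(as.integer(warm_months)),
                 cold = sort(as.integer(cold_months))),
            class = "oz_seasons")
}

#' Season label of dates
#'
#' @param date A Date vector.
#' @param seasons A [season_spec()].
#' @return Character vector, `"warm"` or `"cold"`.
#' @export
season_of <- function(date, seasons = season_spec()) {
  ifelse(lubridate::month(date) %in% seasons$warm, "warm", "cold")
}

#' Inclusive day count of a calendar period
#'
#' Gregorian calendar-day count including both endpoints; the reference
#' historical window 2013-04-27..2015-10-31 spans 918 days.
#'
#' @param start_date,end_date Dates (or strings coercible to Date).
#' @return Integer day count.
#' @export
#' @examples
#' count_days_in_period("2013-04-27", "2015-10-31") # 918
count_days_in_period <- function(start_date, end_date) {
  s <- as.Date(start_date); e <- as.Date(end_date)
  if (e < s) abort("end_date precedes start_date")
  as.integer(e - s) + 1L
}

#' Convert an ozone mass concentration to a mixing ratio
#'
#' Uses the fixed conversion 2.0 ug/m3 per ppb (ozone at standard reporting
#' conditions), consistent with the WHO guideline equivalence 100 ug/m3
#' ~ 50 ppb.
#'
#' @param value Concentration in ug/m3 (vectorized, non-negative).
#' @return Concentration in ppb.
#' @export
#' @examples
#' convert_ugm3_to_ppb(100) # 50
convert_ugm3_to_ppb <- function(value) {
  if (any(value < 0, na.rm = TRUE)) abort("negative concentration")
  value / UGM3_PER_PPB
}

#' Conversion factor: micrograms per cubic meter per ppb of ozone
#' @export
UGM3_PER_PPB <- 2.0
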