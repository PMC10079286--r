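# Calendar time is represented as an absolute month index: ym(2020, 4) is
# April 2020. Natural-history event times are continuous (fractional months);
# screening happens on whole months.

#' Absolute month index for a calendar year and month
#'
#' The simulation clock is an integer month index, `12 * year + (month - 1)`,
#' so arithmetic on screening intervals is plain integer arithmetic and any
#' index converts back to a calendar date unambiguously.
#'
#' @param year Calendar year (integer vector).
#' @param month Calendar month 1-12 (integer vector, default 1).
#' @return Integer month index.
#' @examples
#' ym(2020, 4) - ym(2018, 4) # 24 months
#' @export
ym <- function(year, month = 1L) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer(12L * year + (month - 1L))
}

#' Convert a month index back to calendar year and month
#'
#' @param m Integer month index as produced by [ym()].
#' @return A tibble with columns `year` and `month`.
#' @export
ym_decode <- function(m) {
  m <- as.integer(floor(m))
  tibble::tibble(year = m %/% 12L, month = m %% 12L + 1L)
}

#' Calendar year of a month index (vectorised)
#' @param m Month index (may be fractional; floored).
#' @return Integer year.
#' @export
ym_year <- function(m) as.integer(floor(m) %/% 12L)

#' Convert months to weeks
#'
#' Uses the mean Gregorian month length (365.25 / 12 days), so 24 months is
#' reported as 104.3 weeks, matching routine programme reporting.
#'
#' @param months Numeric vector of month counts.
#' @return Numeric vector of week counts.
#' @export
months_to_weeks <- function(months) months * (365.25 / 12 / 7)
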