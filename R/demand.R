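#' Annual viral-load testing demand for a clinic
#'
#' Estimates the expected number of viral-load samples a clinic generates per
#' year from its HIV client volumes. Children are tested twice per year;
#' adults average 1.08 tests per year (semi-annual testing in the first
#' treatment year, annual thereafter), so
#' `annual = 2 * child_volume + 1.08 * adult_volume`.
#'
#' @param child_volume Number of children living with HIV seen per year.
#' @param adult_volume Number of adults living with HIV seen per year.
#' @return Expected samples per year (numeric, vectorized).
#' @examples
#' estimate_annual_demand(100, 1000) # 1280
#' @export
estimate_annual_demand <- function(child_volume, adult_volume) {
  if (any(child_volume < 0) || any(adult_volume < 0)) {
    stop("client volumes must be non-negative", call. = FALSE)
  }
  2 * child_volume + 1.08 * adult_volume
}

#' Daily viral-load testing demand
#'
#' Converts annual demand into samples per working day, using a fixed number
#' of workdays per month (default 20, i.e. 240 working days per year).
#' Demand is kept at full precision; the steady-state model treats it as a
#' fluid rate, not an integer count.
#'
#' @param annual_demand Samples per year.
#' @param workdays_per_month Working days per month (default 20).
#' @return Samples per working day.
#' @examples
#' estimate_daily_demand(2400) # 10
#' @export
estimate_daily_demand <- function(annual_demand, workdays_per_month = 20) {
  if (any(annual_demand < 0)) {
    stop("annual demand must be non-negative", call. = FALSE)
  }
  if (any(workdays_per_month <= 0)) {
    stop("workdays_per_month must be positive", call. = FALSE)
  }
  annual_demand / (12 * workdays_per_month)
}
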