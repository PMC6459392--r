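#' Mammography unit throughput parameters
#'
#' Parameters of the standard (INCA technical note) annual production formula
#' for one mammography unit: exams/hour x shift hours x working days/month x
#' months x performance factor. The defaults are the reference values
#' (3 exams/hour, 8 h shift, 22 working days, 12 months, 80% performance),
#' which yield 5 069 exams per machine-year.
#'
#' @param exams_per_hour exams performed per hour of operation (default 3).
#' @param shift_hours length of the daily shift in hours (default 8).
#' @param working_days_per_month working days per month (default 22).
#' @param months_per_year months of operation per year (default 12).
#' @param performance effective fraction of nominal capacity achieved,
#'   in (0, 1] (default 0.80); absorbs routine maintenance and minor downtime.
#' @return an object of class `throughput_params`.
#' @examples
#' annual_capacity(throughput_params()) # 5069
#' @export
throughput_params <- function(exams_per_hour = 3,
                              shift_hours = 8,
                              working_days_per_month = 22,
                              months_per_year = 12,
                              performance = 0.80) {
  check_positive(exams_per_hour, "exams_per_hour")
  check_positive(shift_hours, "shift_hours")
  check_positive(working_days_per_month, "working_days_per_month")
  check_positive(months_per_year, "months_per_year")
  check_positive(performance, "performance")
  if (performance > 1) {
    stop_domain("`performance` must lie in (0, 1]")
  }
  structure(
    list(exams_per_hour = exams_per_hour,
         shift_hours = shift_hours,
         working_days_per_month = as.integer(working_days_per_month),
         months_per_year = as.integer(months_per_year),
         performance = performance),
    class = "throughput_params"
  )
}

#' Working-day calendar for a simulation horizon
#'
#' @param horizon_months number of months in the planning horizon
#'   (default 24, one two-year screening cycle).
#' @param include_saturdays if `TRUE`, Saturdays are worked: the month grows
#'   from 22 to 26 working days (22 x 1.2 rounded to the nearest day — the
#'   one-extra-day-per-week uplift quoted weekly as +20%).
#' @return an object of class `screening_calendar`.
#' @seealso [working_days()], [saturday_uplift_percent()]
#' @export
screening_calendar <- function(horizon_months = 24, include_saturdays = FALSE) {
  check_positive(horizon_months, "horizon_months")
  if (horizon_months != as.integer(horizon_months)) {
    stop_domain("`horizon_months` must be a whole number of months")
  }
  structure(
    list(horizon_months = as.integer(horizon_months),
         include_saturdays = isTRUE(include_saturdays)),
    class = "screening_calendar"
  )
}

days_per_month <- function(calendar) {
  if (calendar$include_saturdays) 26L else 22L
}

#' Annual exam capacity of one mammography unit
#'
#' `round(exams_per_hour * shift_hours * working_days_per_month *
#' months_per_year * performance)`, rounded half-up to a whole exam.
#' With the default parameters this is 5 069 exams per machine-year.
#'
#' @param params a [throughput_params()] object.
#' @return integer number of exams per machine-year.
#' @export
annual_capacity <- function(params = throughput_params()) {
  stopifnot(inherits(params, "throughput_params"))
  raw <- params$exams_per_hour * params$shift_hours *
    params$working_days_per_month * params$months_per_year *
    params$performance
  as.integer(round_half_up(raw))
}

#' Daily exam capacity of one mammography unit
#'
#' Effective exams per working day: `exams_per_hour * shift_hours *
#' performance` (19.2 at the defaults; 24 nominal at performance 1).
#'
#' @inheritParams annual_capacity
#' @return exams per working day (real).
#' @export
daily_capacity <- function(params = throughput_params()) {
  stopifnot(inherits(params, "throughput_params"))
  params$exams_per_hour * params$shift_hours * params$performance
}

#' Total working days in a calendar horizon
#'
#' @param calendar a [screening_calendar()] object.
#' @return integer: `horizon_months * 22` (Saturdays off) or
#'   `horizon_months * 26` (Saturdays worked).
#' @export
working_days <- function(calendar = screening_calendar()) {
  stopifnot(inherits(calendar, "screening_calendar"))
  calendar$horizon_months * days_per_month(calendar)
}

#' Weekly supply uplift from working Saturdays
#'
#' One extra working day on a five-day week: `100 * (6/5 - 1) = 20`.
#' At month granularity the calendar rounds 22 x 1.2 = 26.4 to 26 days,
#' so the realised uplift over a horizon is slightly below 20%
#' (96/528 = 18.2% over 24 months); this function returns the weekly figure.
#'
#' @return percent increase in weekly exam supply (20).
#' @export
saturday_uplift_percent <- function() {
  100 * (6 / 5 - 1)
}
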