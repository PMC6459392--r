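#' Possible exams from machine-years of operation
#'
#' Capacity of `machine_years` of fixed-unit operation at a given annual
#' throughput: `round(machine_years * annual_capacity)`, half-up.
#'
#' @param machine_years nonnegative real, machine-years of operation.
#' @param capacity_per_year integer exams per machine-year (default
#'   [annual_capacity()] at the reference parameters, 5 069).
#' @return integer number of exams possible.
#' @examples
#' possible_exams(6)  # 30414
#' possible_exams(12) # 60828
#' @export
possible_exams <- function(machine_years,
                           capacity_per_year = annual_capacity()) {
  check_nonnegative(machine_years, "machine_years")
  check_positive(capacity_per_year, "capacity_per_year")
  as.integer(round_half_up(machine_years * capacity_per_year))
}

#' Coverage percentage
#'
#' `100 * exams / eligible`, rounded half-up to one decimal. Returns 0 when
#' the eligible population is zero (with a warning: synthetic regions may
#' contain empty municipalities). Values above 100 are legitimate — supply
#' (or exams pacted in from other municipalities) can exceed local demand.
#'
#' @param exams nonnegative number of exams (realized or possible).
#' @param eligible nonnegative eligible population.
#' @return percent, one decimal.
#' @examples
#' coverage_pct(39315, 108098) # 36.4
#' coverage_pct(4535, 2405)    # 188.6
#' @export
coverage_pct <- function(exams, eligible) {
  check_nonnegative(exams, "exams")
  check_nonnegative(eligible, "eligible")
  if (eligible == 0) {
    if (exams > 0) warning("coverage_pct: eligible population is 0; returning 0")
    return(0)
  }
  round_half_up(100 * exams / eligible, 1)
}

#' Capacity utilization percentage
#'
#' `100 * exams_total / possible_total`, rounded half-up to one decimal.
#'
#' @param exams_total total exams realized.
#' @param possible_total total exams possible (> 0).
#' @return percent, one decimal.
#' @examples
#' utilization_pct(39315, 197691) # 19.9
#' @export
utilization_pct <- function(exams_total, possible_total) {
  check_nonnegative(exams_total, "exams_total")
  if (!is.numeric(possible_total) || length(possible_total) != 1L ||
      is.na(possible_total) || possible_total <= 0) {
    stop_domain("`possible_total` must be positive")
  }
  round_half_up(100 * exams_total / possible_total, 1)
}

#' Build the coverage report for a region
#'
#' The deterministic accounting that turns a region plus a set of exam
#' counts (observed, or produced by [run_simulation()]) into the standard
#' per-municipality coverage table: possible exams (machine-years x annual
#' capacity), possible coverage, achieved coverage, plus a regional totals
#' row and the overall capacity utilization. Totals-row percentages are
#' recomputed from the column sums, never averaged over rows.
#'
#' @param region a [screening_region()].
#' @param exams_by_municipality named integer vector or list mapping
#'   municipality id to exams performed; missing ids count as 0. Defaults to
#'   the region's observed `exams_realized` column.
#' @param params a [throughput_params()] giving the annual capacity.
#' @return an object of class `coverage_report`: list with `rows` (data
#'   frame, one row per municipality in region order), `totals` (one-row
#'   data frame for the region) and `utilization_pct`.
#' @examples
#' region <- load_region_fixture("serrana_2015_2016")
#' rep <- build_coverage_report(region)
#' rep$totals$achieved_coverage_pct # 36.4
#' rep$utilization_pct              # 19.9
#' @export
build_coverage_report <- function(region,
                                  exams_by_municipality = NULL,
                                  params = throughput_params()) {
  stopifnot(inherits(region, "screening_region"))
  m <- region$municipalities
  if (is.null(exams_by_municipality)) {
    exams <- m$exams_realized
    names(exams) <- m$id
  } else {
    exams_by_municipality <- unlist(exams_by_municipality)
    unknown <- setdiff(names(exams_by_municipality), m$id)
    if (length(unknown)) {
      stop_validation(paste0("unknown municipality id(s) in exam counts: ",
                             paste(unknown, collapse = ", ")))
    }
    exams <- setNames(rep(0, nrow(m)), m$id)
    exams[names(exams_by_municipality)] <- exams_by_municipality
  }
  cap_year <- annual_capacity(params)
  possible <- vapply(m$machine_years_observed, possible_exams,
                     integer(1), capacity_per_year = cap_year)
  rows <- data.frame(
    municipality_id = m$id,
    name = m$name,
    eligible = m$eligible_population,
    fixed_units = m$fixed_units,
    possible_exams = possible,
    possible_coverage_pct = mapply(coverage_pct, possible,
                                   m$eligible_population),
    exams_realized = as.integer(round(exams[m$id])),
    achieved_coverage_pct = mapply(coverage_pct, exams[m$id],
                                   m$eligible_population),
    stringsAsFactors = FALSE
  )
  rownames(rows) <- NULL
  tot_eligible <- sum(rows$eligible)
  tot_possible <- sum(rows$possible_exams)
  tot_exams <- sum(rows$exams_realized)
  totals <- data.frame(
    municipality_id = "TOTAL",
    name = "Region total",
    eligible = tot_eligible,
    fixed_units = sum(rows$fixed_units),
    possible_exams = tot_possible,
    possible_coverage_pct = coverage_pct(tot_possible, tot_eligible),
    exams_realized = tot_exams,
    achieved_coverage_pct = coverage_pct(tot_exams, tot_eligible),
    stringsAsFactors = FALSE
  )
  structure(
    list(rows = rows, totals = totals,
         utilization_pct = if (tot_possible > 0) {
           utilization_pct(tot_exams, tot_possible)
         } else 0),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  print(x$rows, row.names = FALSE)
  cat("--\n")
  print(x$totals, row.names = FALSE)
  cat(sprintf("capacity utilization: %.1f%%\n", x$utilization_pct))
  invisible(x)
}

#' Write a coverage report as CSV
#'
#' Columns follow the standard table order (eligible population, fixed
#' units, possible exams, possible coverage, exams realized, achieved
#' coverage); the totals row is appended last.
#'
#' @param report a [build_coverage_report()] result.
#' @param path output CSV path.
#' @param comma_decimals if `TRUE`, percentages are written with a decimal
#'   comma for side-by-side comparison with pt-BR sources.
#' @return invisibly, `path`.
#' @export
write_coverage_report <- function(report, path, comma_decimals = FALSE) {
  stopifnot(inherits(report, "coverage_report"))
  out <- rbind(report$rows, report$totals)
  if (comma_decimals) {
    for (col in c("possible_coverage_pct", "achieved_coverage_pct")) {
      out[[col]] <- sub(".", ",", sprintf("%.1f", out[[col]]), fixed = TRUE)
    }
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
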