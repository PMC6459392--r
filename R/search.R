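#' Fixed-unit placement rule
#'
#' Allocates fixed units to the municipalities where a full-time installed
#' unit is justified by local demand: for each municipality, let
#' `q = target_fraction * eligible / (exams_per_day * working_days)` be the
#' local target demand measured in unit-horizons. Municipalities with
#' `q >= 0.5` (local demand fills at least half a unit) receive `ceiling(q)`
#' fixed units; the rest are left to mobile units. On the packaged serrana
#' region at 24 exams/day over 24 months this yields 3 + 2 + 2 = 7 fixed
#' units (Petropolis, Nova Friburgo, Teresopolis) for a 100% target and
#' 2 + 2 + 1 = 5 for a 60% target.
#'
#' @param region a [screening_region()].
#' @param target_coverage_pct target supply coverage in (0, 100].
#' @param exams_per_day daily production per unit.
#' @param horizon_days working days in the planning horizon.
#' @return named integer vector municipality id -> fixed units (only
#'   municipalities receiving at least one unit).
#' @export
allocate_fixed_units <- function(region, target_coverage_pct = 100,
                                 exams_per_day = 24, horizon_days = 528) {
  stopifnot(inherits(region, "screening_region"))
  check_positive(target_coverage_pct, "target_coverage_pct")
  check_positive(exams_per_day, "exams_per_day")
  check_positive(horizon_days, "horizon_days")
  m <- region$municipalities
  unit_output <- exams_per_day * horizon_days
  q <- (target_coverage_pct / 100) * m$eligible_population / unit_output
  n <- ifelse(q >= 0.5, ceiling(q), 0L)
  out <- setNames(as.integer(n), m$id)
  out[out > 0L]
}

#' Find the minimum fleet reaching a coverage target
#'
#' Simulation search for the smallest fleet whose final regional supply
#' coverage reaches the target. The fixed component is set by the placement
#' rule ([allocate_fixed_units()]) or by an explicit placement; the mobile
#' count is then the free variable, increased one unit at a time from a
#' capacity lower bound until the target is met (each candidate evaluated
#' by [run_simulation()]). Deterministic given the config seed.
#'
#' @param region a [screening_region()].
#' @param target_coverage_pct target supply coverage in (0, 100].
#' @param config a [simulation_config()].
#' @param fixed_placement optional named vector overriding the placement
#'   rule.
#' @param max_mobile search bound on the mobile count (default 50).
#' @return an object of class `scenario_result`: list with `n_fixed`,
#'   `n_mobile`, `fixed_placement`, `exams_per_day`, `target_coverage_pct`,
#'   `final_coverage_pct`, `feasible`, and the winning `trajectory` (`NULL`
#'   when infeasible within the bound).
#' @examples
#' region <- generate_synthetic_region(2, 2000, seed = 1)
#' res <- find_min_fleet(region, 50,
#'                       simulation_config(screening_calendar(3)))
#' res$n_mobile
#' @export
find_min_fleet <- function(region, target_coverage_pct = 100,
                           config = simulation_config(),
                           fixed_placement = NULL,
                           max_mobile = 50L) {
  stopifnot(inherits(region, "screening_region"),
            inherits(config, "simulation_config"))
  if (target_coverage_pct <= 0 || target_coverage_pct > 100) {
    stop_domain("`target_coverage_pct` must lie in (0, 100]")
  }
  horizon <- working_days(config$calendar)
  if (is.null(fixed_placement)) {
    fixed_placement <- allocate_fixed_units(
      region, target_coverage_pct, config$exams_per_day, horizon)
  }
  m <- region$municipalities
  eligible <- setNames(m$eligible_population, m$id)
  total_eligible <- sum(eligible)
  target_exams <- (target_coverage_pct / 100) * total_eligible
  unit_output <- config$exams_per_day * horizon

  # fixed units only serve their home municipality
  fixed_usable <- sum(pmin(
    unlist(fixed_placement) * unit_output,
    eligible[names(fixed_placement)]))
  lb_mobile <- max(0L, ceiling((target_exams - fixed_usable) / unit_output))

  search_range <- if (lb_mobile <= max_mobile) lb_mobile:max_mobile
                  else integer()
  for (n_mobile in search_range) {
    fleet <- make_fleet(fixed_placement, n_mobile, region)
    traj <- run_simulation(region, fleet, config)
    if (traj$final_coverage_pct >= target_coverage_pct) {
      return(structure(
        list(n_fixed = sum(fixed_placement),
             n_mobile = as.integer(n_mobile),
             fixed_placement = fixed_placement,
             exams_per_day = config$exams_per_day,
             target_coverage_pct = target_coverage_pct,
             final_coverage_pct = traj$final_coverage_pct,
             feasible = TRUE,
             trajectory = traj),
        class = "scenario_result"))
    }
  }
  structure(
    list(n_fixed = sum(fixed_placement),
         n_mobile = NA_integer_,
         fixed_placement = fixed_placement,
         exams_per_day = config$exams_per_day,
         target_coverage_pct = target_coverage_pct,
         final_coverage_pct = NA_real_,
         feasible = FALSE,
         trajectory = NULL,
         bound_failed = sprintf(
           "no fleet with up to %d mobile units reached %.1f%%",
           max_mobile, target_coverage_pct)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf(
      "<scenario_result> %d units (%d fixed + %d mobile) at %.0f exams/day -> %.1f%% (target %.1f%%)\n",
      x$n_fixed + x$n_mobile, x$n_fixed, x$n_mobile, x$exams_per_day,
      x$final_coverage_pct, x$target_coverage_pct))
    placement <- paste(sprintf("%s:%d", names(x$fixed_placement),
                               x$fixed_placement), collapse = ", ")
    cat("  fixed placement:", placement, "\n")
  } else {
    cat(sprintf("<scenario_result> INFEASIBLE: %s\n", x$bound_failed))
  }
  invisible(x)
}

#' Sensitivity sweep over daily production
#'
#' Re-runs one simulation per value of `exams_per_day`, all other settings
#' identical, and tabulates the final coverage reached.
#'
#' @param region a [screening_region()].
#' @param fleet list of [mammograph_unit()].
#' @param exams_per_day_values positive daily production values, e.g.
#'   `c(4, 12, 24)`.
#' @param config a [simulation_config()]; its `exams_per_day` is replaced by
#'   each sweep value in turn.
#' @return data frame with columns `exams_per_day` and
#'   `final_coverage_pct`, one row per value in input order; the
#'   trajectories are attached as the `"trajectories"` attribute.
#' @export
sensitivity_sweep <- function(region, fleet, exams_per_day_values,
                              config = simulation_config()) {
  if (!length(exams_per_day_values)) {
    return(data.frame(exams_per_day = numeric(),
                      final_coverage_pct = numeric()))
  }
  for (v in exams_per_day_values) check_positive(v, "exams_per_day_values")
  trajs <- lapply(exams_per_day_values, function(v) {
    cfg <- config
    cfg$exams_per_day <- v
    run_simulation(region, fleet, cfg)
  })
  out <- data.frame(
    exams_per_day = exams_per_day_values,
    final_coverage_pct = vapply(trajs, `[[`, numeric(1),
                                "final_coverage_pct")
  )
  attr(out, "trajectories") <- trajs
  out
}

#' Percent reduction of a fleet relative to a baseline
#'
#' `round(100 * (baseline - scenario) / baseline)`, half-up to a whole
#' percent. A scenario of 8 units against the 22 installed is a 64%
#' reduction; 11 against 22 is 50%.
#'
#' @param baseline_units installed units (> 0).
#' @param scenario_units units in the proposed scenario.
#' @return integer percent reduction.
#' @examples
#' fleet_reduction_pct(22, 8)  # 64
#' fleet_reduction_pct(22, 11) # 50
#' @export
fleet_reduction_pct <- function(baseline_units, scenario_units) {
  check_positive(baseline_units, "baseline_units")
  check_nonnegative(scenario_units, "scenario_units")
  as.integer(round_half_up(
    100 * (baseline_units - scenario_units) / baseline_units))
}
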