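#' Define a mammography unit
#'
#' @param id unique unit id (e.g. `"fx1"`, `"mob2"`).
#' @param kind `"fixed"` (installed in a facility, never moves) or
#'   `"mobile"` (relocatable along the road network).
#' @param location home municipality (fixed) or starting municipality
#'   (mobile).
#' @param exams_per_day optional per-unit override of the fleet-wide daily
#'   production set in [simulation_config()].
#' @return an object of class `mammograph_unit`.
#' @export
mammograph_unit <- function(id, kind = c("fixed", "mobile"), location,
                            exams_per_day = NULL) {
  kind <- match.arg(kind)
  if (!is.null(exams_per_day)) check_positive(exams_per_day, "exams_per_day")
  structure(list(id = as.character(id), kind = kind,
                 location = as.character(location),
                 exams_per_day = exams_per_day),
            class = "mammograph_unit")
}

#' Build a fleet from a fixed placement and a mobile count
#'
#' @param fixed_placement named integer vector: municipality id -> number of
#'   fixed units installed there. May be empty.
#' @param n_mobile number of mobile units.
#' @param region a [screening_region()]; mobile units start distributed
#'   round-robin over municipalities in descending order of eligible
#'   population (the first unit at the largest).
#' @return list of [mammograph_unit()] objects, fixed units first.
#' @export
make_fleet <- function(fixed_placement = integer(), n_mobile = 0,
                       region = NULL) {
  fleet <- list()
  k <- 0L
  for (muni in names(fixed_placement)) {
    n <- fixed_placement[[muni]]
    if (n > 0) {
      for (i in seq_len(n)) {
        k <- k + 1L
        fleet[[length(fleet) + 1L]] <-
          mammograph_unit(sprintf("fx%02d", k), "fixed", muni)
      }
    }
  }
  if (n_mobile > 0) {
    stopifnot(!is.null(region))
    m <- region$municipalities
    starts <- m$id[order(-m$eligible_population, m$id)]
    for (i in seq_len(n_mobile)) {
      fleet[[length(fleet) + 1L]] <- mammograph_unit(
        sprintf("mob%02d", i), "mobile",
        starts[((i - 1L) %% length(starts)) + 1L])
    }
  }
  fleet
}

#' Simulation configuration
#'
#' All run-time parameters of the daily-step simulator.
#'
#' @param calendar a [screening_calendar()] (default: 24 months, Saturdays
#'   off, i.e. 528 working days).
#' @param exams_per_day fleet-wide daily production per unit (default 24,
#'   the nominal recommendation; sensitivity values of interest are 12
#'   and 4). Fractional values are supported via a per-unit carry-over.
#' @param dwell_days consecutive working days a mobile unit stays in a
#'   municipality before relocating (default 5); it leaves earlier if the
#'   municipality is fully screened.
#' @param travel_days_per_move whole working days consumed by a relocation
#'   (default 1; 0 means moves are free).
#' @param routing_criterion one of [routing_criteria()] (default
#'   `"weighted_distance"`).
#' @param rotation_scope `"per_unit"` (each mobile unit keeps its own
#'   rotation ledger; default) or `"fleet"` (one shared ledger: a
#'   municipality visited by any unit is off-limits to all until the cycle
#'   completes).
#' @param alpha demand weight of [weighted_edge_cost()].
#' @param seed integer seed; all stochastic components (downtime) draw from
#'   it, so equal seeds give identical trajectories.
#' @param downtime_enabled if `TRUE`, units suffer scheduled maintenance and
#'   random breakdowns (default `FALSE`: routine downtime is already
#'   inside the throughput performance factor).
#' @param scheduled_days_per_year evenly spaced maintenance days per year
#'   per unit (used when `downtime_enabled`).
#' @param breakdown_prob_per_day per-day breakdown probability (used when
#'   `downtime_enabled`).
#' @param repair_days working days lost per breakdown.
#' @param serve_rural_first if `TRUE`, units serve the rural zone of a
#'   municipality before the urban zone (default urban first).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(calendar = screening_calendar(),
                              exams_per_day = 24,
                              dwell_days = 5,
                              travel_days_per_move = 1,
                              routing_criterion = "weighted_distance",
                              rotation_scope = c("per_unit", "fleet"),
                              alpha = 0.001,
                              seed = 1L,
                              downtime_enabled = FALSE,
                              scheduled_days_per_year = 12,
                              breakdown_prob_per_day = 0.002,
                              repair_days = 3,
                              serve_rural_first = FALSE) {
  stopifnot(inherits(calendar, "screening_calendar"))
  check_positive(exams_per_day, "exams_per_day")
  check_positive(dwell_days, "dwell_days")
  check_nonnegative(travel_days_per_move, "travel_days_per_move")
  routing_criterion <- match.arg(routing_criterion, routing_criteria())
  rotation_scope <- match.arg(rotation_scope)
  check_positive(alpha, "alpha")
  check_nonnegative(scheduled_days_per_year, "scheduled_days_per_year")
  if (breakdown_prob_per_day < 0 || breakdown_prob_per_day >= 1) {
    stop_domain("`breakdown_prob_per_day` must lie in [0, 1)")
  }
  check_positive(repair_days, "repair_days")
  structure(
    list(calendar = calendar,
         exams_per_day = exams_per_day,
         dwell_days = as.integer(dwell_days),
         travel_days_per_move = as.integer(travel_days_per_move),
         routing_criterion = routing_criterion,
         rotation_scope = rotation_scope,
         alpha = alpha,
         seed = as.integer(seed),
         downtime_enabled = isTRUE(downtime_enabled),
         scheduled_days_per_year = as.integer(scheduled_days_per_year),
         breakdown_prob_per_day = breakdown_prob_per_day,
         repair_days = as.integer(repair_days),
         serve_rural_first = isTRUE(serve_rural_first)),
    class = "simulation_config"
  )
}

#' Per-unit idle days from scheduled maintenance and random breakdowns
#'
#' Scheduled maintenance days are deterministic and evenly spaced through
#' each working year; breakdowns start with a fixed per-day probability and
#' idle the unit for `repair_days` consecutive days. Draws come from the
#' given seed, so schedules are reproducible.
#'
#' @param horizon_days number of working days simulated.
#' @param scheduled_days_per_year evenly spaced maintenance days per year.
#' @param breakdown_prob_per_day per-day breakdown probability in \[0, 1).
#' @param repair_days days lost per breakdown.
#' @param days_per_year working days in one year (264 for a 22-day month).
#' @param seed integer seed for the breakdown draws.
#' @return sorted integer vector of idle day indices (1-based).
#' @export
downtime_idle_days <- function(horizon_days,
                               scheduled_days_per_year = 12,
                               breakdown_prob_per_day = 0,
                               repair_days = 3,
                               days_per_year = 264,
                               seed = 1L) {
  check_positive(horizon_days, "horizon_days")
  idle <- integer()
  if (scheduled_days_per_year > 0) {
    gap <- days_per_year / scheduled_days_per_year
    sched <- round(seq(gap, days_per_year, by = gap))
    all_years <- as.vector(outer(sched, (seq_len(ceiling(
      horizon_days / days_per_year)) - 1L) * days_per_year, `+`))
    idle <- all_years[all_years <= horizon_days]
  }
  if (breakdown_prob_per_day > 0) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(as.integer(seed))
    starts <- which(runif(horizon_days) < breakdown_prob_per_day)
    broken <- unique(unlist(lapply(starts, function(s)
      s:min(s + repair_days - 1L, horizon_days))))
    idle <- union(idle, broken)
  }
  sort(as.integer(idle))
}

# initial unscreened counts per municipality x zone
init_unscreened <- function(region) {
  m <- region$municipalities
  urban <- round(m$eligible_population * m$urban_fraction)
  out <- cbind(urban = urban, rural = m$eligible_population - urban)
  rownames(out) <- m$id
  out
}

# serve up to `budget` exams from a municipality row of the unscreened
# matrix; returns list(matrix, performed)
serve_municipality <- function(unscreened, muni, budget, rural_first) {
  zones <- if (rural_first) c("rural", "urban") else c("urban", "rural")
  done <- 0
  for (z in zones) {
    take <- min(budget - done, unscreened[muni, z])
    unscreened[muni, z] <- unscreened[muni, z] - take
    done <- done + take
    if (done >= budget) break
  }
  list(unscreened = unscreened, performed = done)
}

#' Run the screening simulation
#'
#' The daily-step engine. Each working day, every available unit performs
#' up to its daily production, limited by the unscreened women remaining in
#' its municipality (supply coverage: every offered slot is taken while
#' unscreened women remain). Fixed units serve their home municipality;
#' mobile units dwell for `dwell_days`, then relocate along the road
#' network to the next stop chosen by the routing criterion under the
#' round-robin rotation guarantee, spending `travel_days_per_move` days in
#' transit. A mobile unit leaves early when its municipality is fully
#' screened, and stays put only when it is the sole remaining destination.
#'
#' @param region a [screening_region()].
#' @param fleet list of [mammograph_unit()] (e.g. from [make_fleet()]); may
#'   be empty (zero coverage).
#' @param config a [simulation_config()].
#' @return an object of class `screening_trajectory`: list with
#'   \describe{
#'     \item{daily}{data frame: `day`, `exams` (that day), `cumulative_exams`,
#'       `regional_coverage_pct` (exact, not rounded), `unscreened_total`.}
#'     \item{exams_by_municipality}{named vector of total exams performed.}
#'     \item{municipal_coverage_pct}{day x municipality matrix of cumulative
#'       coverage.}
#'     \item{events}{data frame of mobile relocations and downtime: `day`,
#'       `unit`, `event`, `from`, `to`, `cycle`.}
#'     \item{final_coverage_pct}{final regional supply coverage, one decimal.}
#'     \item{report}{the final [build_coverage_report()] under simulated
#'       exams.}
#'   }
#' @examples
#' region <- generate_synthetic_region(3, 3000, seed = 1)
#' fleet <- make_fleet(n_mobile = 1, region = region)
#' traj <- run_simulation(region, fleet,
#'                        simulation_config(screening_calendar(2)))
#' traj$final_coverage_pct
#' @export
run_simulation <- function(region, fleet, config = simulation_config()) {
  stopifnot(inherits(region, "screening_region"),
            inherits(config, "simulation_config"))
  m <- region$municipalities
  ids <- m$id
  horizon <- working_days(config$calendar)
  for (u in fleet) {
    if (!inherits(u, "mammograph_unit")) {
      stop_validation("fleet elements must be mammograph_unit objects")
    }
    if (!u$location %in% ids) {
      stop_validation(sprintf("unit '%s' placed at unknown municipality '%s'",
                              u$id, u$location))
    }
  }
  if (anyDuplicated(vapply(fleet, `[[`, "", "id"))) {
    stop_validation("duplicated unit id in fleet")
  }

  unscreened <- init_unscreened(region)
  total_eligible <- sum(m$eligible_population)

  units <- lapply(fleet, function(u) {
    list(id = u$id, kind = u$kind, location = u$location,
         rate = if (is.null(u$exams_per_day)) config$exams_per_day
                else u$exams_per_day,
         carry = 0,
         dwell_remaining = config$dwell_days,
         travel_remaining = 0L,
         visited = character(),   # per-unit rotation (ignored in fleet scope)
         destinations = NULL,
         cycle = 1L,
         done = FALSE)
  })
  names(units) <- vapply(fleet, `[[`, "", "id")

  # shared ledger for fleet-scope rotation
  shared <- list(visited = character(), destinations = NULL, cycle = 1L)

  idle_days <- lapply(seq_along(units), function(i) {
    if (config$downtime_enabled) {
      downtime_idle_days(
        horizon,
        scheduled_days_per_year = config$scheduled_days_per_year,
        breakdown_prob_per_day = config$breakdown_prob_per_day,
        repair_days = config$repair_days,
        days_per_year = days_per_month(config$calendar) * 12L,
        seed = config$seed + i)
    } else integer()
  })

  # initialise mobile rotation: the starting municipality counts as visited
  mobile_idx <- which(vapply(units, `[[`, "", "kind") == "mobile")
  start_dest <- ids[rowSums(unscreened) > 0]
  for (i in mobile_idx) {
    units[[i]]$destinations <- start_dest
    units[[i]]$visited <- intersect(units[[i]]$location, start_dest)
  }
  if (config$rotation_scope == "fleet" && length(mobile_idx)) {
    shared$destinations <- start_dest
    shared$visited <- intersect(
      unique(vapply(units[mobile_idx], `[[`, "", "location")), start_dest)
  }

  daily_exams <- numeric(horizon)
  cum_by_muni <- setNames(numeric(length(ids)), ids)
  muni_cov <- matrix(0, nrow = horizon, ncol = length(ids),
                     dimnames = list(NULL, ids))
  events <- vector("list", 0L)
  log_event <- function(day, unit, event, from, to, cycle) {
    events[[length(events) + 1L]] <<- data.frame(
      day = day, unit = unit, event = event, from = from, to = to,
      cycle = cycle, stringsAsFactors = FALSE)
  }

  for (day in seq_len(horizon)) {
    for (i in seq_along(units)) {
      u <- units[[i]]
      if (day %in% idle_days[[i]]) {
        log_event(day, u$id, "downtime", u$location, u$location,
                  NA_integer_)
        next
      }
      if (u$kind == "mobile" && u$travel_remaining > 0L) {
        u$travel_remaining <- u$travel_remaining - 1L
        if (u$travel_remaining == 0L) {
          u$dwell_remaining <- config$dwell_days
        }
        units[[i]] <- u
        next
      }

      budget_raw <- u$rate + u$carry
      budget <- floor(budget_raw)
      u$carry <- budget_raw - budget

      if (budget > 0) {
        srv <- serve_municipality(unscreened, u$location, budget,
                                  config$serve_rural_first)
        unscreened <- srv$unscreened
        daily_exams[day] <- daily_exams[day] + srv$performed
        cum_by_muni[u$location] <- cum_by_muni[u$location] + srv$performed
      }

      if (u$kind == "mobile") {
        u$dwell_remaining <- u$dwell_remaining - 1L
        exhausted <- sum(unscreened[u$location, ]) == 0
        if (exhausted || u$dwell_remaining <= 0L) {
          totals <- rowSums(unscreened)
          use_shared <- config$rotation_scope == "fleet"
          visited <- if (use_shared) shared$visited else u$visited
          dest <- if (use_shared) shared$destinations else u$destinations
          cycle_no <- if (use_shared) shared$cycle else u$cycle
          candidates <- setdiff(dest, visited)
          candidates <- candidates[totals[candidates] > 0]
          if (!length(candidates)) {
            # cycle complete (or all its remaining towns screened):
            # start a new cycle over currently unscreened municipalities
            dest <- ids[totals > 0]
            visited <- character()
            candidates <- dest
            cycle_no <- cycle_no + 1L
          }
          if (!length(candidates)) {
            u$done <- TRUE           # region fully screened
            u$dwell_remaining <- config$dwell_days
          } else {
            nxt <- select_next_stop(u$location, candidates, region,
                                    totals, config$routing_criterion,
                                    config$alpha)
            visited <- union(visited, nxt)
            if (use_shared) {
              shared$visited <- visited
              shared$destinations <- dest
              shared$cycle <- cycle_no
            } else {
              u$visited <- visited
              u$destinations <- dest
              u$cycle <- cycle_no
            }
            if (!identical(nxt, u$location)) {
              log_event(day, u$id, "move", u$location, nxt, cycle_no)
              u$location <- nxt
              if (config$travel_days_per_move > 0L) {
                u$travel_remaining <- config$travel_days_per_move
              } else {
                u$dwell_remaining <- config$dwell_days
              }
            } else {
              u$dwell_remaining <- config$dwell_days
            }
          }
        }
      }
      units[[i]] <- u
    }
    muni_cov[day, ] <- ifelse(m$eligible_population > 0,
                              100 * cum_by_muni / m$eligible_population, 0)
  }

  cum <- cumsum(daily_exams)
  # conservation: screened + unscreened = eligible, per municipality
  stopifnot(all(abs(cum_by_muni + rowSums(unscreened) -
                      m$eligible_population) < 1e-9))

  daily <- data.frame(
    day = seq_len(horizon),
    exams = daily_exams,
    cumulative_exams = cum,
    regional_coverage_pct = 100 * cum / total_eligible,
    unscreened_total = total_eligible - cum
  )
  events_df <- if (length(events)) do.call(rbind, events) else
    data.frame(day = integer(), unit = character(), event = character(),
               from = character(), to = character(), cycle = integer(),
               stringsAsFactors = FALSE)

  structure(
    list(daily = daily,
         exams_by_municipality = cum_by_muni,
         municipal_coverage_pct = muni_cov,
         events = events_df,
         final_coverage_pct = round_half_up(
           100 * sum(cum_by_muni) / total_eligible, 1),
         report = build_coverage_report(region, as.list(cum_by_muni)),
         config = config,
         n_fixed = sum(vapply(units, `[[`, "", "kind") == "fixed"),
         n_mobile = length(mobile_idx)),
    class = "screening_trajectory"
  )
}

#' @export
print.screening_trajectory <- function(x, ...) {
  cat(sprintf(
    "<screening_trajectory> %d working days, %d fixed + %d mobile units\n",
    nrow(x$daily), x$n_fixed, x$n_mobile))
  cat(sprintf("  exams performed: %d   final supply coverage: %.1f%%\n",
              as.integer(sum(x$exams_by_municipality)),
              x$final_coverage_pct))
  invisible(x)
}
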