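one_town <- function(pop = 100) tiny_region(pop, urban = 0.5)

test_that("a single fixed unit screens its town at the capacity rate, then idles", {
  region <- one_town(100)
  fleet <- make_fleet(c(t01 = 1L), 0, region)
  traj <- run_simulation(region, fleet,
                         simulation_config(exams_per_day = 10, seed = 1))
  expect_equal(traj$daily$cumulative_exams[10], 100)
  expect_equal(traj$daily$regional_coverage_pct[10], 100)
  # flat afterwards: no further exams once everyone is screened
  expect_true(all(traj$daily$exams[11:nrow(traj$daily)] == 0))
  expect_equal(traj$final_coverage_pct, 100)
})

test_that("an empty fleet yields zero coverage", {
  traj <- run_simulation(one_town(), list(), simulation_config())
  expect_equal(traj$final_coverage_pct, 0)
  expect_true(all(traj$daily$exams == 0))
})

test_that("daily exams are demand-capped, not summed over unit capacity", {
  region <- one_town(30)
  fleet <- make_fleet(c(t01 = 2L), 0, region)
  traj <- run_simulation(region, fleet,
                         simulation_config(exams_per_day = 24, seed = 1))
  expect_equal(traj$daily$exams[1], 30)  # not 48
  expect_equal(traj$daily$exams[2], 0)
})

test_that("degenerate single-town runs hit min(eligible, capacity) exactly", {
  cal <- screening_calendar(2)  # 44 working days
  for (pop in c(50, 500, 5000)) {
    for (n_units in 1:2) {
      region <- one_town(pop)
      fleet <- make_fleet(setNames(as.integer(n_units), "t01"), 0, region)
      traj <- run_simulation(region, fleet, simulation_config(
        calendar = cal, exams_per_day = 10, travel_days_per_move = 0,
        seed = 1))
      expect_equal(sum(traj$exams_by_municipality),
                   min(pop, n_units * 10 * 44),
                   label = sprintf("pop %d, %d units", pop, n_units))
    }
  }
})

test_that("fractional daily capacity accumulates exactly via carry-over", {
  region <- one_town(1000)
  fleet <- make_fleet(c(t01 = 1L), 0, region)
  traj <- run_simulation(region, fleet, simulation_config(
    calendar = screening_calendar(1), exams_per_day = 2.5, seed = 1))
  expect_equal(sum(traj$exams_by_municipality), floor(2.5 * 22))
})

test_that("conservation, monotonicity and the fleet capacity bound hold on mixed fleets", {
  region <- serrana()
  fleet <- make_fleet(c(petropolis = 1L, nova_friburgo = 1L), 2, region)
  cfg <- simulation_config(calendar = screening_calendar(6), seed = 3)
  traj <- run_simulation(region, fleet, cfg)
  m <- region$municipalities
  # conservation: exams never exceed the eligible population anywhere
  expect_true(all(traj$exams_by_municipality <=
                    setNames(m$eligible_population, m$id)))
  expect_equal(sum(traj$exams_by_municipality),
               traj$daily$cumulative_exams[nrow(traj$daily)])
  # regional coverage nondecreasing in time
  expect_true(all(diff(traj$daily$regional_coverage_pct) >= -1e-12))
  expect_true(all(diff(traj$daily$cumulative_exams) >= 0))
  # per-municipality coverage series nondecreasing and capped at 100
  expect_true(all(apply(traj$municipal_coverage_pct, 2,
                        function(x) all(diff(x) >= -1e-12))))
  expect_true(all(traj$municipal_coverage_pct <= 100 + 1e-9))
  # strict capacity bound
  expect_lte(sum(traj$exams_by_municipality),
             length(fleet) * cfg$exams_per_day * working_days(cfg$calendar))
})

test_that("identical seeds give identical trajectories, including under downtime", {
  region <- serrana()
  fleet <- make_fleet(c(petropolis = 2L), 2, region)
  cfg <- simulation_config(calendar = screening_calendar(6), seed = 11,
                           downtime_enabled = TRUE,
                           breakdown_prob_per_day = 0.01)
  t1 <- run_simulation(region, fleet, cfg)
  t2 <- run_simulation(region, fleet, cfg)
  expect_identical(t1$daily, t2$daily)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$exams_by_municipality, t2$exams_by_municipality)
  # a different seed changes the breakdown pattern
  cfg2 <- cfg; cfg2$seed <- 12L
  t3 <- run_simulation(region, fleet, cfg2)
  expect_false(identical(t1$events, t3$events))
})

test_that("rotation: within one cycle a unit never revisits a municipality", {
  region <- serrana()
  for (scope in c("per_unit", "fleet")) {
    traj <- run_simulation(
      region, make_fleet(integer(), 3, region),
      simulation_config(calendar = screening_calendar(8),
                        rotation_scope = scope, seed = 2))
    moves <- traj$events[traj$events$event == "move", ]
    expect_gt(nrow(moves), 10)
    if (scope == "per_unit") {
      key <- paste(moves$unit, moves$cycle)
    } else {
      key <- moves$cycle  # shared ledger: uniqueness across the whole fleet
    }
    dup <- tapply(moves$to, key, function(x) anyDuplicated(x) > 0)
    expect_false(any(dup), label = paste("scope", scope))
  }
})

test_that("downtime idles units as scheduled and by seeded breakdowns", {
  # breakdowns off: no idle days beyond the scheduled ones
  expect_identical(
    downtime_idle_days(264, scheduled_days_per_year = 0,
                       breakdown_prob_per_day = 0),
    integer())
  # 12 scheduled days over a 12-month (264-working-day) horizon
  sched <- downtime_idle_days(264, scheduled_days_per_year = 12,
                              breakdown_prob_per_day = 0)
  expect_length(sched, 12L)
  expect_true(all(diff(sched) == 22))
  # binomial sanity: ~100 breakdown starts in 10000 days at p = 0.01
  idle <- downtime_idle_days(10000, scheduled_days_per_year = 0,
                             breakdown_prob_per_day = 0.01,
                             repair_days = 1, seed = 42)
  expect_gt(length(idle), 100 - 3 * sqrt(10000 * 0.01 * 0.99))
  expect_lt(length(idle), 100 + 3 * sqrt(10000 * 0.01 * 0.99))
  # downtime strictly reduces throughput on a busy region
  region <- serrana()
  fleet <- make_fleet(c(petropolis = 2L), 0, region)
  base <- run_simulation(region, fleet,
                         simulation_config(calendar = screening_calendar(6),
                                           seed = 5))
  down <- run_simulation(region, fleet,
                         simulation_config(calendar = screening_calendar(6),
                                           seed = 5, downtime_enabled = TRUE,
                                           scheduled_days_per_year = 12,
                                           breakdown_prob_per_day = 0.02))
  expect_lt(sum(down$exams_by_municipality), sum(base$exams_by_municipality))
})

test_that("invalid fleets and configs are rejected by name", {
  region <- one_town()
  expect_error(
    run_simulation(region, make_fleet(c(narnia = 1L), 0, region),
                   simulation_config()),
    class = "mammofleet_validation_error")
  expect_error(simulation_config(dwell_days = 0),
               class = "mammofleet_domain_error")
  expect_error(simulation_config(travel_days_per_move = -1),
               class = "mammofleet_domain_error")
  expect_error(simulation_config(breakdown_prob_per_day = 1),
               class = "mammofleet_domain_error")
  expect_error(simulation_config(routing_criterion = "teleport"))
})
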