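---
title: "Planning mixed fixed/mobile mammography fleets: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning mixed fixed/mobile mammography fleets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammofleet)
```

## The problem

Screening mammography coverage is limited less by the number of installed
machines than by where they are and how intensively they run. A region can
hold capacity for almost twice its eligible population and still screen
barely a third of it, because fixed units cluster in a few cities while
women elsewhere depend on inter-municipal referral pacts that work poorly
in practice. `mammofleet` models the supply side of this problem: given a
region of municipalities connected by roads, how much coverage can a fleet
of fixed and mobile units *offer* within one two-year screening cycle, and
what is the smallest fleet that offers a target coverage?

## Model

### Demand

Women eligible for screening are modelled as counts per municipality and
zone (urban/rural), not as individual agents. At the model's daily
resolution and with deterministic service, an individual-level population
is behaviourally identical to a counted one, and counts keep runs fast and
exactly reproducible. Each municipality starts with
`round(eligible * urban_fraction)` urban women, the remainder rural;
screening depletes these counts and nothing replenishes them within a
cycle (screened + unscreened = eligible at every step, an invariant the
engine asserts).

### Supply

A unit's reference annual output is the standard technical-note formula:
3 exams/hour × 8 h shift × 22 working days/month × 12 months × 80%
performance = 5 069 exams per machine-year (`annual_capacity()`, rounded
half-up). The simulator instead takes a *daily* production per unit
(`exams_per_day`), because the scenarios of interest vary it directly:
24/day is the nominal recommendation, 12/day is half production, and
observed regional production has been far lower still. The 80% performance
factor is understood as already containing routine maintenance; explicit
downtime (evenly spaced scheduled maintenance days plus seeded random
breakdowns with a repair time) is available but off by default.

### Movement

Fixed units serve their home municipality only — the model deliberately
excludes women travelling between municipalities, since mispredicting that
referral flow is part of the problem being addressed. Mobile units occupy
one municipality at a time, serve its urban zone then its rural zone (the
order is configurable), and relocate when the municipality is fully
screened or their dwell time expires. Relocation follows shortest road
paths; route choice among candidate destinations uses one of five
criteria, and a rotation ledger guarantees every destination municipality
is visited once per cycle before any revisit. The destination set of a
cycle is the set of municipalities with unscreened women at cycle start,
so units never spend dwell periods in fully screened towns.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `exams_per_day` | 24 | exams/unit/day | nominal recommended daily production |
| `dwell_days` | 5 | working days | one working week per stop; the sources name the parameter but no value |
| `travel_days_per_move` | 1 | working days | relocation costs one day regardless of distance; no speed/turnaround data exist, distances still drive route choice |
| `routing_criterion` | `weighted_distance` | — | the demand-weighted Dijkstra variant; four simpler criteria available |
| `alpha` | 0.001 | per woman | 1 000 unscreened women halve an edge's effective distance |
| `rotation_scope` | `per_unit` | — | each unit keeps its own ledger; a fleet-wide shared ledger is available |
| `horizon_months` | 24 | months | one two-year screening cycle, 528 working days |
| `include_saturdays` | `FALSE` | — | Saturdays add one day per five-day week (+20% weekly supply; 26-day months at month granularity, 22 × 1.2 = 26.4 rounded to 26) |

The demand-weighted edge cost is `distance / (1 + alpha * unscreened)`.
The functional form is a package design choice (the criterion is described
in the field only as "a function of distance and the population still to
be screened"); it reduces to plain distance at zero demand, is strictly
monotone in both arguments, and `alpha` is exposed so alternative
weightings can be compared.

### Adherence

Coverage here is *supply* coverage: every offered exam slot is taken while
unscreened women remain. This is the model's optimistic upper bound — it
answers "could the fleet offer everyone an exam?", not "would everyone
come?". No-shows, referral friction and cultural barriers are outside the
model.

## Design choices made where the design was open

**Fixed placement rule.** Printed scenario results fix only the total
fixed-unit count and, for one scenario, the city split. The rule used
throughout the package allocates, for a target fraction *t*, a city with
eligible population *E* exactly `ceiling(q)` fixed units where
`q = t·E / (exams_per_day × working_days)` is local target demand in
unit-horizons — but only when `q ≥ 0.5`, i.e. when demand fills at least
half a full-time unit. On the packaged region at 24 exams/day over 24
months this yields 3 Petrópolis + 2 Nova Friburgo + 2 Teresópolis = 7
fixed units at a 100% target and 2 + 2 + 1 = 5 at a 60% target, matching
both published configurations. A plain greedy allocation by remaining
demand reproduces the first split but not the second (it over-serves the
largest city), which is why the threshold rule was chosen.

**Initial mobile placement.** Mobile units start distributed round-robin
over municipalities in descending eligible-population order (unit 1 in the
largest). Their starting municipality counts as the first visit of their
first rotation cycle.

**Tie-breaking.** Exact criterion ties are broken by lexicographic
municipality id, making `select_next_stop()` a pure function of its
inputs; determinism of whole trajectories follows (asserted byte-identical
in tests).

**Fractional production.** Non-integer `exams_per_day` accumulates in a
per-unit carry so long-run throughput is exact (2.5/day over 22 days gives
exactly 55 exams).

**Degenerate inputs.** Zero eligible population yields 0% coverage with a
warning rather than an error (synthetic regions may contain empty
municipalities); an empty fleet simulates to zero coverage; a
single-municipality region has an empty road network and mobile units
simply stay put.

## Rounding

Percentages are rounded half-up to one decimal
(`floor(10x + 0.5) / 10`), not by banker's rounding — the convention was
verified against all fourteen nonzero printed percentages of the reference
coverage table (e.g. 41.685 → 41.7, 537.538 → 537.5, 19.887 → 19.9).
Annual capacity rounds 5 068.8 half-up to 5 069. Regional totals are
recomputed from column sums, never averaged over rows.

## The packaged region and what the simulations show

```{r fixture}
region <- load_region_fixture("serrana_2015_2016")
build_coverage_report(region)$totals
```

With observed exams the report reproduces the published coverage table
cell-for-cell: 197 691 possible exams (182.9% possible coverage) against
39 315 realized (36.4% achieved, 19.9% utilization).

```{r scenario}
fixed7 <- allocate_fixed_units(region, 100, 24, 528)
fleet <- make_fleet(fixed7, n_mobile = 4, region = region)
traj <- run_simulation(region, fleet, simulation_config(seed = 1))
traj
plot(traj$daily$day, traj$daily$regional_coverage_pct, type = "l",
     xlab = "working day", ylab = "regional supply coverage (%)")
```

Seven fixed plus four mobile units at 24 exams/day reach 100% supply
coverage within the 24-month horizon; the same fleet at 12 exams/day still
clears the 60% pact target. `find_min_fleet()` recovers the 11-unit
configuration by search, and removing one mobile unit makes the 100%
target fail — the searched fleet is minimal under these settings.

A note on the 60% target: the published 60% scenario (5 fixed + 3 mobile
= 8 units) is a *validation* of the redistributed design, not a
minimal-fleet search result; under this package's defaults the regional
60% target is already reachable with fewer units, because regional supply
coverage can be concentrated where demand is densest. The 8-unit
configuration is therefore asserted in tests as a given fleet that clears
60%, while `find_min_fleet(region, 60, ...)` may legitimately return a
smaller fleet.

## What the synthetic generator does and does not emulate

`generate_synthetic_region()` produces heavy-tailed (lognormal) municipal
populations apportioned exactly to a requested total, a connected random
road graph (random spanning tree plus extra edges, 10-90 km distances),
and fixed units concentrated where local demand justifies them. It mimics
the *structural* features the engine is sensitive to — size skew,
connectivity, sparse equipment — and is the workhorse of the property
tests. It does not emulate spatial autocorrelation of population, real
highway geometry, referral flows between regions, or observed utilization
patterns; passing tests on synthetic regions therefore validate the
engine's mechanics and invariants, not the realism of any particular
regional forecast.

## Problem sizes used in the test suite

Simulation tests run the packaged 16-municipality region over 4-24 month
horizons (88-528 working days) with fleets of up to 11 units, and the
shortest-path oracle checks 100 random graphs of 3-7 nodes against
exhaustive simple-path enumeration. These sizes exercise every code path
(rotation resets, early exhaustion, zone switching, downtime) while
keeping the full suite fast enough to run habitually.

## Limitations

- Supply coverage is an upper bound; adherence, staffing and diagnostic
  follow-up are out of scope.
- Travel consumes a fixed number of working days irrespective of distance;
  distances matter for *where* units go, not *how long* they take.
- Exams are attributed to the performing municipality, so the model cannot
  express residence-based coverage reallocation (no origin-destination
  data exist at this resolution).
- The road distances shipped with the fixture are a plausible synthetic
  reconstruction; results that depend on capacity identities are robust to
  them, per-municipality trajectory shapes are not.
- The fleet search varies the mobile count for a rule-determined fixed
  placement; it does not search the combinatorial space of fixed/mobile
  splits (an explicit placement override is available).
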