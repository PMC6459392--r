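# mammofleet

Capacity planning for population-based breast-cancer screening programmes
that mix **fixed** mammography units (installed in facilities) with
**mobile** units (truck-mounted, relocating along the road network).

The package is aimed at health-services researchers and regional programme
managers who need to answer questions like: *how many units, fixed where
and mobile on which routes, does a region need to offer every eligible
woman a mammogram within one two-year screening cycle?*

## What it computes

**Throughput accounting.** The annual capacity of one unit follows the
standard technical-note formula

```
annual capacity = exams/hour × shift hours × working days/month × months × performance
                = 3 × 8 × 22 × 12 × 0.80 = 5 069 exams per machine-year
```

**Coverage accounting.** For each municipality *i* with eligible
population *E<sub>i</sub>*, machine-years of operation *y<sub>i</sub>*, and
exams realized *x<sub>i</sub>*:

- possible exams: *P<sub>i</sub>* = round(*y<sub>i</sub>* × 5 069)
- possible coverage: 100 *P<sub>i</sub>* / *E<sub>i</sub>* (may exceed 100%)
- achieved coverage: 100 *x<sub>i</sub>* / *E<sub>i</sub>*
- utilization: 100 Σ*x<sub>i</sub>* / Σ*P<sub>i</sub>*

with percentages rounded half-up to one decimal, and regional totals
recomputed from column sums.

**Agent-based simulation.** A daily-step simulator in which every unit
performs up to its daily production, limited by the unscreened women
remaining in its municipality and zone (urban/rural). Mobile units dwell a
configurable number of working days, then relocate along shortest road
paths (Dijkstra) to the next stop chosen by one of five criteria —
percent unscreened, absolute unscreened, smallest population, shortest
distance, or a demand-weighted distance where an edge into a town with
*u* unscreened women costs *d* / (1 + α·*u*) — under a round-robin
rotation guarantee: every destination municipality is visited once per
cycle before any revisit.

**Scenario search.** `find_min_fleet()` places fixed units where local
demand justifies a full-time installation and then grows the mobile count
one unit at a time until a target supply coverage is reached.

## Worked example

The packaged fixture `serrana_2015_2016` describes the serrana region of
Rio de Janeiro state (16 municipalities, 108 098 eligible women, 22 fixed
units) in the 2015-2016 biennium:

```r
library(mammofleet)

region <- load_region_fixture("serrana_2015_2016")
rep <- build_coverage_report(region)
rep$totals[, c("eligible", "fixed_units", "possible_exams",
               "possible_coverage_pct", "exams_realized",
               "achieved_coverage_pct")]
#>   eligible fixed_units possible_exams possible_coverage_pct exams_realized achieved_coverage_pct
#> 1   108098          22         197691                 182.9          39315                  36.4
rep$utilization_pct
#> [1] 19.9
```

The 22 installed units could have covered the region 1.8 times over, yet
only 36.4% of eligible women were screened, at 19.9% of capacity — the
motivation for redistributing the fleet. Simulating a redistributed fleet
of 7 fixed + 4 mobile units at 24 exams/day over 24 working months:

```r
fixed7 <- allocate_fixed_units(region, 100, exams_per_day = 24,
                               horizon_days = 528)
fixed7
#> nova_friburgo    petropolis   teresopolis
#>             2             3             2
fleet <- make_fleet(fixed7, n_mobile = 4, region = region)
run_simulation(region, fleet, simulation_config(seed = 1))
#> <screening_trajectory> 528 working days, 7 fixed + 4 mobile units
#>   exams performed: 108098   final supply coverage: 100.0%
```

Eleven units — half of the 22 installed (`fleet_reduction_pct(22, 11)` is
50) — suffice for full supply coverage; at half the daily production
(12 exams/day) the same fleet still reaches 60.3%, the pact target.
`find_min_fleet(region, 100, simulation_config(seed = 1))` recovers the
same 7 + 4 configuration by search.

A thin command-line front-end (`inst/cli/mammofleet.R`) exposes
`summarize`, `simulate`, `optimize` and `generate` subcommands over YAML
scenario configs.

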