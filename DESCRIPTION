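Package: mammofleet
Title: Agent-Based Simulation of Mammography Screening Coverage with
    Fixed and Mobile Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capacity planning of population-based breast cancer
    screening programmes that combine fixed mammography units with mobile
    (truck-mounted) units travelling along a road network. Provides the
    standard throughput accounting for mammography capacity (exams per hour,
    shift length, working days, performance factor), deterministic coverage
    and utilization reports for a region of municipalities, a daily-step
    agent-based simulator in which mobile units dwell in and relocate between
    municipalities under configurable routing criteria with a round-robin
    rotation guarantee, and a scenario search that finds the minimum fleet
    reaching a target supply coverage. Ships a worked regional fixture (16
    municipalities of the serrana region of Rio de Janeiro state, biennium
    2015-2016) and a seeded synthetic-region generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
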