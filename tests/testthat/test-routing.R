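test_that("shortest paths match hand-checked small cases", {
  # triangle where the two-hop route beats the direct edge
  tri <- tiny_region(c(100, 100, 100),
                     edges = data.frame(id_a = c("t01", "t02", "t01"),
                                        id_b = c("t02", "t03", "t03"),
                                        distance_km = c(2, 2, 5)))
  sp <- road_shortest_paths(tri, "t01")
  expect_equal(sp$distance_km[["t03"]], 4)
  expect_identical(sp$path[["t03"]], c("t01", "t02", "t03"))
  expect_equal(sp$distance_km[["t01"]], 0)
  expect_identical(sp$path[["t01"]], "t01")

  line <- tiny_region(c(10, 10, 10), edges = line_edges(3, c(1, 1)))
  expect_equal(road_shortest_paths(line, "t01")$distance_km[["t03"]], 2)

  expect_error(road_shortest_paths(tri, "t99"),
               class = "mammofleet_not_found_error")
})

test_that("shortest-path distances equal the brute-force simple-path oracle", {
  n_graphs <- 0
  for (seed in 1:100) {
    n <- 3 + seed %% 5   # 3..7 nodes
    edges <- random_connected_edges(n, seed)
    region <- tiny_region(rep(100, n), edges = edges)
    ids <- region$municipalities$id
    src <- ids[1 + seed %% n]
    sp <- road_shortest_paths(region, src)
    for (to in ids) {
      expect_equal(sp$distance_km[[to]],
                   brute_force_distance(edges, ids, src, to),
                   tolerance = 1e-9,
                   label = sprintf("seed %d, %s->%s", seed, src, to))
    }
    n_graphs <- n_graphs + 1
  }
  expect_gte(n_graphs, 100)
})

test_that("demand-weighted edge cost discounts distance by unmet demand", {
  expect_equal(weighted_edge_cost(10, 0, 0.5), 10)
  expect_equal(weighted_edge_cost(10, 1000, 0.001), 5)
  expect_lt(weighted_edge_cost(10, 2000, 0.001),
            weighted_edge_cost(10, 1000, 0.001))
  expect_gt(weighted_edge_cost(20, 500, 0.001),
            weighted_edge_cost(10, 500, 0.001))
  expect_error(weighted_edge_cost(0, 10), class = "mammofleet_domain_error")
})

test_that("rotation ledger resets exactly when the destination set is covered", {
  led <- new_rotation_ledger("u1")
  led <- record_visit(led, "u1", "A", c("A", "B", "C"))
  expect_identical(led$visited$u1, "A")
  expect_identical(led$cycle_count[["u1"]], 0L)
  led <- record_visit(led, "u1", "C", c("A", "B", "C"))
  led <- record_visit(led, "u1", "B", c("A", "B", "C"))
  expect_identical(led$visited$u1, character(0))
  expect_identical(led$cycle_count[["u1"]], 1L)
  expect_error(record_visit(led, "u1", "Z", c("A", "B")),
               class = "mammofleet_domain_error")
})

test_that("next-stop selection optimises each criterion with lexicographic ties", {
  region <- tiny_region(c(1000, 400, 2000), edges = line_edges(3, c(10, 30)))
  unscreened <- c(t01 = 500, t02 = 300, t03 = 500)

  # 75% unscreened beats 50%
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), region, unscreened,
                     "percent_unscreened"), "t02")
  # absolute count prefers the 500-women town
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), region, unscreened,
                     "absolute_unscreened"), "t01")
  # smallest population
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), region, unscreened,
                     "smallest_population"), "t02")
  # nearest by road from t03: t02 at 30 vs t01 at 40
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), region, unscreened,
                     "shortest_distance"), "t02")
  # weighted distance: strong demand at t01 overturns plain distance
  # (t01 is 12 km from t03, t02 only 10, but 5000 unscreened at t01
  # discount its edge to 2 effective km)
  tri <- tiny_region(c(10000, 400, 2000),
                     edges = data.frame(id_a = c("t01", "t02", "t01"),
                                        id_b = c("t02", "t03", "t03"),
                                        distance_km = c(10, 10, 12)))
  u2 <- c(t01 = 5000, t02 = 0, t03 = 0)
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), tri, u2,
                     "shortest_distance"), "t02")
  expect_identical(
    select_next_stop("t03", c("t01", "t02"), tri, u2,
                     "weighted_distance"), "t01")

  # single candidate is forced, regardless of criterion
  for (crit in routing_criteria()) {
    expect_identical(
      select_next_stop("t01", "t03", region, unscreened, crit), "t03")
  }
  # exact tie broken lexicographically
  tie <- c(t01 = 300, t02 = 300, t03 = 0)
  region_tie <- tiny_region(c(600, 600, 100), edges = line_edges(3, c(10, 10)))
  expect_identical(
    select_next_stop("t03", c("t02", "t01"), region_tie, tie,
                     "absolute_unscreened"), "t01")
  # determinism: identical inputs, identical choice
  pick <- replicate(5, select_next_stop(
    "t03", c("t01", "t02"), region, unscreened, "weighted_distance"))
  expect_identical(unique(pick), pick[1])

  expect_error(
    select_next_stop("t01", character(), region, unscreened),
    class = "mammofleet_domain_error")
})
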