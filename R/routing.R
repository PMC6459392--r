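#' Shortest road paths from one municipality
#'
#' Single-source shortest paths over the region's road network (classic
#' Dijkstra; edge weights are distances in km, always positive).
#'
#' @param region a [screening_region()].
#' @param source municipality id.
#' @return list with `distance_km` (named numeric vector over all
#'   municipalities, 0 at the source, `Inf` for unreachable nodes) and
#'   `path` (named list of id sequences from source to each municipality).
#' @examples
#' region <- load_region_fixture("serrana_2015_2016")
#' sp <- road_shortest_paths(region, "petropolis")
#' sp$distance_km[["teresopolis"]] # 40
#' @export
road_shortest_paths <- function(region, source) {
  stopifnot(inherits(region, "screening_region"))
  ids <- region$municipalities$id
  if (!source %in% ids) {
    stop_not_found(sprintf("unknown source municipality '%s'", source))
  }
  g <- region_graph(region)
  d <- igraph::distances(g, v = source, algorithm = "dijkstra")[1L, ]
  paths <- igraph::shortest_paths(g, from = source, to = igraph::V(g),
                                  output = "vpath")$vpath
  path_ids <- lapply(paths, function(p) igraph::as_ids(p))
  names(path_ids) <- ids
  # igraph returns an empty path for unreachable vertices
  path_ids[[source]] <- source
  list(distance_km = d[ids], path = path_ids)
}

#' Demand-weighted edge cost
#'
#' The routing variant that biases shortest-path relocation towards
#' municipalities with many unscreened women: an edge into a municipality
#' with `u` unscreened women costs `distance_km / (1 + alpha * u)`. The cost
#' is strictly increasing in distance and strictly decreasing in unmet
#' demand; at `u = 0` it reduces to the plain distance.
#'
#' @param distance_km positive road distance in km.
#' @param unscreened_at_target nonnegative count of unscreened women at the
#'   edge's target municipality.
#' @param alpha demand weight per woman (default 0.001: one thousand
#'   unscreened women halve the effective distance).
#' @return edge cost (real).
#' @examples
#' weighted_edge_cost(10, 0)    # 10
#' weighted_edge_cost(10, 1000) # 5
#' @export
weighted_edge_cost <- function(distance_km, unscreened_at_target,
                               alpha = 0.001) {
  check_positive(distance_km, "distance_km")
  check_nonnegative(unscreened_at_target, "unscreened_at_target")
  check_positive(alpha, "alpha")
  distance_km / (1 + alpha * unscreened_at_target)
}

# All-pairs-from-source path costs under the demand-weighted cost:
# directed copy of the road graph, edge u->v weighted by
# weighted_edge_cost(d(u,v), unscreened[v], alpha).
weighted_path_costs <- function(region, source, unscreened, alpha = 0.001) {
  ids <- region$municipalities$id
  r <- region$roads
  if (nrow(r) == 0L) {
    return(setNames(ifelse(ids == source, 0, Inf), ids))
  }
  u <- setNames(rep(0, length(ids)), ids)
  u[names(unscreened)] <- unscreened
  edges <- data.frame(
    from = c(r$id_a, r$id_b),
    to = c(r$id_b, r$id_a),
    stringsAsFactors = FALSE
  )
  w <- c(r$distance_km, r$distance_km) / (1 + alpha * u[edges$to])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = ids)
  d <- igraph::distances(g, v = source, mode = "out", weights = w,
                         algorithm = "dijkstra")[1L, ]
  d[ids]
}

#' Create a rotation ledger
#'
#' The rotation ("rodizio") mechanism guarantees that a mobile unit visits
#' every municipality in its destination set once per cycle before any
#' revisit. The ledger tracks, per unit, the municipalities already visited
#' in the current cycle and the number of completed cycles.
#'
#' @param unit_ids character vector of mobile unit ids.
#' @return an object of class `rotation_ledger`.
#' @seealso [record_visit()], [select_next_stop()]
#' @export
new_rotation_ledger <- function(unit_ids) {
  structure(
    list(visited = setNames(lapply(unit_ids, function(i) character()),
                            unit_ids),
         cycle_count = setNames(integer(length(unit_ids)), unit_ids)),
    class = "rotation_ledger"
  )
}

#' Record a mobile unit's visit in the rotation ledger
#'
#' Adds the municipality to the unit's visited set. When the visited set
#' reaches the unit's full destination set the cycle completes: the visited
#' set clears and `cycle_count` increments.
#'
#' @param ledger a [new_rotation_ledger()].
#' @param unit mobile unit id.
#' @param municipality municipality id being visited.
#' @param destination_set character vector of all municipalities the unit
#'   must cover this cycle.
#' @return the updated ledger.
#' @export
record_visit <- function(ledger, unit, municipality, destination_set) {
  stopifnot(inherits(ledger, "rotation_ledger"))
  if (!municipality %in% destination_set) {
    stop_domain(sprintf(
      "municipality '%s' is not in the unit's destination set", municipality))
  }
  visited <- union(ledger$visited[[unit]], municipality)
  if (setequal(visited, destination_set)) {
    ledger$visited[[unit]] <- character()
    ledger$cycle_count[[unit]] <- ledger$cycle_count[[unit]] + 1L
  } else {
    ledger$visited[[unit]] <- visited
  }
  ledger
}

#' Routing criteria for mobile units
#'
#' @return character vector of the recognised criterion names:
#'   `percent_unscreened` (go where the largest share of the population is
#'   still unscreened), `absolute_unscreened` (largest count of unscreened
#'   women), `smallest_population` (smallest eligible population, reducing
#'   revisits), `shortest_distance` (nearest by road), and
#'   `weighted_distance` (nearest by the demand-weighted cost of
#'   [weighted_edge_cost()]).
#' @export
routing_criteria <- function() {
  c("percent_unscreened", "absolute_unscreened", "smallest_population",
    "shortest_distance", "weighted_distance")
}

#' Select a mobile unit's next stop
#'
#' Among rotation-eligible municipalities (the candidates), returns the
#' arg-optimum of the chosen criterion. Ties are broken by lexicographic
#' municipality id so the choice is a pure, reproducible function of its
#' inputs. The unit's current municipality is never chosen unless it is the
#' only candidate.
#'
#' @param current municipality id where the unit currently is.
#' @param candidates character vector of rotation-eligible municipality ids
#'   (destination set minus already-visited); must be nonempty.
#' @param region a [screening_region()].
#' @param unscreened named numeric vector: unscreened women per municipality
#'   (totals over zones).
#' @param criterion one of [routing_criteria()].
#' @param alpha demand weight for `weighted_distance`.
#' @return the chosen municipality id.
#' @export
select_next_stop <- function(current, candidates, region, unscreened,
                             criterion = "weighted_distance",
                             alpha = 0.001) {
  criterion <- match.arg(criterion, routing_criteria())
  if (length(candidates) == 0L) {
    stop_domain("no rotation-eligible municipality (ledger reset contract violated)")
  }
  if (length(candidates) > 1L) {
    candidates <- setdiff(candidates, current)
  }
  m <- region$municipalities
  eligible_pop <- setNames(m$eligible_population, m$id)
  u <- setNames(rep(0, nrow(m)), m$id)
  u[names(unscreened)] <- unscreened

  score <- switch(
    criterion,
    percent_unscreened = -ifelse(eligible_pop[candidates] > 0,
                                 u[candidates] / eligible_pop[candidates], 0),
    absolute_unscreened = -u[candidates],
    smallest_population = eligible_pop[candidates],
    shortest_distance = road_shortest_paths(region, current)$distance_km[candidates],
    weighted_distance = weighted_path_costs(region, current, u,
                                            alpha)[candidates]
  )
  # minimise score; lexicographic id among exact ties
  best <- candidates[score == min(score)]
  sort(best)[1L]
}
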