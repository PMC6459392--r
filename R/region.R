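#' Construct a screening region
#'
#' A region is the planning unit of a screening programme: a set of
#' municipalities (each with an eligible female population split into urban
#' and rural zones, its installed fixed mammography units, and observed
#' operation/production figures) joined by an undirected road network with
#' distances in km. Women are represented as counts per municipality and
#' zone, the resolution at which supply coverage is defined.
#'
#' @param municipalities data frame with columns `id` (unique short token),
#'   `name`, `eligible_population` (nonnegative integer, women eligible over
#'   one screening cycle), `urban_fraction` (in \[0, 1\]), `fixed_units`
#'   (nonnegative integer), `machine_years_observed` (nonnegative real:
#'   machine-years of fixed-unit operation observed in the cycle),
#'   `exams_realized` (nonnegative integer, counted at the performing
#'   municipality).
#' @param roads data frame with columns `id_a`, `id_b`, `distance_km`
#'   (positive). May have zero rows for a single-municipality region.
#' @param years_in_cycle length of the screening cycle in years (default 2).
#' @return an object of class `screening_region`.
#' @seealso [load_region_fixture()], [generate_synthetic_region()],
#'   [validate_region()]
#' @export
screening_region <- function(municipalities, roads, years_in_cycle = 2) {
  required <- c("id", "name", "eligible_population", "urban_fraction",
                "fixed_units", "machine_years_observed", "exams_realized")
  missing_cols <- setdiff(required, names(municipalities))
  if (length(missing_cols)) {
    stop_validation(paste0("municipality table is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  if (is.null(roads) || nrow(roads) == 0L) {
    roads <- data.frame(id_a = character(), id_b = character(),
                        distance_km = numeric())
  }
  road_cols <- setdiff(c("id_a", "id_b", "distance_km"), names(roads))
  if (length(road_cols)) {
    stop_validation(paste0("road table is missing column(s): ",
                           paste(road_cols, collapse = ", ")))
  }
  check_positive(years_in_cycle, "years_in_cycle")
  municipalities <- as.data.frame(municipalities)[required]
  municipalities$id <- as.character(municipalities$id)
  roads <- as.data.frame(roads)[c("id_a", "id_b", "distance_km")]
  roads$id_a <- as.character(roads$id_a)
  roads$id_b <- as.character(roads$id_b)
  region <- structure(
    list(municipalities = municipalities, roads = roads,
         years_in_cycle = as.integer(years_in_cycle)),
    class = "screening_region"
  )
  problems <- validate_region(region)
  if (length(problems)) {
    stop_validation(paste0("invalid region:\n  ",
                           paste(problems, collapse = "\n  ")))
  }
  region
}

#' @export
print.screening_region <- function(x, ...) {
  m <- x$municipalities
  cat(sprintf(
    "<screening_region> %d municipalities, %d road edges, %d-year cycle\n",
    nrow(m), nrow(x$roads), x$years_in_cycle))
  cat(sprintf("  eligible population: %d   fixed units: %d\n",
              sum(m$eligible_population), sum(m$fixed_units)))
  invisible(x)
}

#' Validate a region against its structural invariants
#'
#' Checks municipality ids for uniqueness, field ranges, the
#' no-units-implies-no-operation rule, road endpoints, positive distances,
#' absence of self loops, and connectivity of the road graph (every
#' municipality reachable from every other). Connectivity is established by
#' traversal of the edge list.
#'
#' @param region a [screening_region()] (or a structurally similar list;
#'   this function reports rather than throws, so it can be used on
#'   candidate regions before construction).
#' @return character vector of violation messages; empty if the region is
#'   valid. Each message names the offending municipality or edge.
#' @export
validate_region <- function(region) {
  m <- region$municipalities
  r <- region$roads
  problems <- character()
  dup <- unique(m$id[duplicated(m$id)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicated municipality id: ",
                                   paste(dup, collapse = ", ")))
  }
  bad <- m$id[m$eligible_population < 0]
  if (length(bad)) {
    problems <- c(problems,
                  paste0("negative eligible_population in: ",
                         paste(bad, collapse = ", ")))
  }
  bad <- m$id[m$urban_fraction < 0 | m$urban_fraction > 1]
  if (length(bad)) {
    problems <- c(problems, paste0("urban_fraction outside [0, 1] in: ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- m$id[m$fixed_units < 0]
  if (length(bad)) {
    problems <- c(problems, paste0("negative fixed_units in: ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- m$id[m$machine_years_observed < 0]
  if (length(bad)) {
    problems <- c(problems, paste0("negative machine_years_observed in: ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- m$id[m$fixed_units == 0 & m$machine_years_observed > 0]
  if (length(bad)) {
    problems <- c(problems,
                  paste0("machine_years_observed > 0 with fixed_units = 0 in: ",
                         paste(bad, collapse = ", ")))
  }
  if (nrow(r)) {
    unknown <- setdiff(c(r$id_a, r$id_b), m$id)
    if (length(unknown)) {
      problems <- c(problems, paste0("road endpoint not a municipality: ",
                                     paste(unknown, collapse = ", ")))
    }
    loops <- which(r$id_a == r$id_b)
    if (length(loops)) {
      problems <- c(problems, paste0("self-loop edge at: ",
                                     paste(r$id_a[loops], collapse = ", ")))
    }
    bad <- which(!is.finite(r$distance_km) | r$distance_km <= 0)
    if (length(bad)) {
      problems <- c(problems,
                    paste0("nonpositive distance on edge(s): ",
                           paste(sprintf("%s-%s", r$id_a[bad], r$id_b[bad]),
                                 collapse = ", ")))
    }
  }
  # connectivity by breadth-first traversal over the edge list
  if (nrow(m) > 1L && !length(problems)) {
    adj <- split(c(r$id_b, r$id_a), c(r$id_a, r$id_b))
    seen <- m$id[1L]
    frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    unreachable <- setdiff(m$id, seen)
    if (length(unreachable)) {
      problems <- c(problems,
                    paste0("road graph disconnected; unreachable from ",
                           m$id[1L], ": ",
                           paste(unreachable, collapse = ", ")))
    }
  }
  problems
}

#' Load a packaged region fixture
#'
#' The packaged fixture `"serrana_2015_2016"` transcribes the observed
#' situation of the serrana region of Rio de Janeiro state over the
#' 2015-2016 biennium: 16 municipalities, their eligible populations,
#' installed fixed mammography units, observed machine-years of operation
#' and exams realized. The fixture's road distances are a synthetic but
#' plausible highway-adjacency table (the source statistics include no
#' distances); they control travel overhead in simulations, not the
#' capacity accounting.
#'
#' @param fixture_name name of a packaged fixture; currently
#'   `"serrana_2015_2016"`.
#' @return a [screening_region()].
#' @examples
#' region <- load_region_fixture("serrana_2015_2016")
#' sum(region$municipalities$eligible_population) # 108098
#' @export
load_region_fixture <- function(fixture_name = "serrana_2015_2016") {
  dir <- system.file("extdata", fixture_name, package = "mammofleet")
  if (!nzchar(dir)) {
    stop_not_found(sprintf("unknown region fixture '%s'", fixture_name))
  }
  read_region(file.path(dir, "municipalities.csv"),
              file.path(dir, "edges.csv"))
}

#' Read a region from its two-file CSV representation
#'
#' @param municipalities_csv path to the municipality table (columns
#'   `id,name,eligible_population,urban_fraction,fixed_units,machine_years_observed,exams_realized`).
#' @param edges_csv path to the edge table (columns `id_a,id_b,distance_km`);
#'   may be missing or empty for single-municipality regions.
#' @return a [screening_region()].
#' @export
read_region <- function(municipalities_csv, edges_csv = NULL) {
  if (!file.exists(municipalities_csv)) {
    stop_not_found(paste0("no such file: ", municipalities_csv))
  }
  m <- read.csv(municipalities_csv, stringsAsFactors = FALSE,
                encoding = "UTF-8")
  if (nrow(m) == 0L) {
    stop_validation("municipality table is empty")
  }
  edges <- NULL
  if (!is.null(edges_csv) && file.exists(edges_csv)) {
    edges <- read.csv(edges_csv, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  screening_region(m, edges)
}

#' Write a region to its two-file CSV representation
#'
#' @param region a [screening_region()].
#' @param dir output directory (created if needed); writes
#'   `municipalities.csv` and `edges.csv`, UTF-8, dot decimal.
#' @return invisibly, the paths written.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "screening_region"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("municipalities.csv", "edges.csv"))
  write.csv(region$municipalities, paths[1L], row.names = FALSE,
            fileEncoding = "UTF-8")
  write.csv(region$roads, paths[2L], row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(paths)
}

#' Generate a synthetic screening region
#'
#' Produces a valid random region for testing and experimentation:
#' municipal populations are drawn from a heavy-tailed (lognormal)
#' distribution and apportioned to sum exactly to `total_population`
#' (largest-remainder method); the road network is a random spanning tree
#' plus extra edges, so it is always connected; fixed units are concentrated
#' in the largest municipalities. The same seed always yields the identical
#' region.
#'
#' @param n_municipalities number of municipalities (>= 1).
#' @param total_population total eligible population of the region.
#' @param seed integer seed.
#' @return a [screening_region()].
#' @examples
#' region <- generate_synthetic_region(5, 10000, seed = 7)
#' validate_region(region) # character(0)
#' @export
generate_synthetic_region <- function(n_municipalities, total_population,
                                      seed = 1L) {
  check_positive(n_municipalities, "n_municipalities")
  check_positive(total_population, "total_population")
  n <- as.integer(n_municipalities)
  total <- as.integer(total_population)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  ids <- sprintf("m%02d", seq_len(n))
  # heavy-tailed municipal sizes, apportioned by largest remainder
  w <- exp(rnorm(n, mean = 0, sd = 1.1))
  quota <- total * w / sum(w)
  pop <- floor(quota)
  short <- total - sum(pop)
  if (short > 0) {
    extra <- order(quota - pop, decreasing = TRUE)[seq_len(short)]
    pop[extra] <- pop[extra] + 1
  }
  urban <- round(runif(n, 0.3, 0.95), 2)

  # fixed units where local demand over the cycle justifies at least half a
  # machine-year of the reference annual output
  unit_cycle_output <- annual_capacity(throughput_params()) * 2
  fixed <- ifelse(pop / unit_cycle_output >= 0.5,
                  pmax(1L, round(pop / unit_cycle_output)), 0L)
  machine_years <- fixed * 2
  util <- runif(n, 0.1, 0.6)
  exams <- as.integer(round(util * machine_years *
                              annual_capacity(throughput_params())))

  roads <- NULL
  if (n > 1L) {
    # random spanning tree: attach each node to a uniformly chosen earlier one
    ord <- sample.int(n)
    a <- integer(0); b <- integer(0)
    for (k in 2:n) {
      a <- c(a, ord[k])
      b <- c(b, ord[sample.int(k - 1L, 1L)])
    }
    n_extra <- max(0L, as.integer(round(n / 3)))
    if (n_extra > 0L) {
      have <- paste(pmin(a, b), pmax(a, b))
      for (i in seq_len(n_extra)) {
        cand <- sample.int(n, 2L)
        key <- paste(min(cand), max(cand))
        if (!(key %in% have)) {
          a <- c(a, cand[1L]); b <- c(b, cand[2L]); have <- c(have, key)
        }
      }
    }
    roads <- data.frame(id_a = ids[a], id_b = ids[b],
                        distance_km = round(runif(length(a), 10, 90), 1))
  }

  screening_region(
    data.frame(id = ids,
               name = paste("Town", toupper(ids)),
               eligible_population = as.integer(pop),
               urban_fraction = urban,
               fixed_units = as.integer(fixed),
               machine_years_observed = machine_years,
               exams_realized = exams,
               stringsAsFactors = FALSE),
    roads
  )
}

# igraph view of the road network (undirected, weighted by km)
region_graph <- function(region) {
  g <- igraph::graph_from_data_frame(
    region$roads[c("id_a", "id_b", "distance_km")],
    directed = FALSE,
    vertices = region$municipalities$id
  )
  igraph::E(g)$weight <- region$roads$distance_km
  g
}
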