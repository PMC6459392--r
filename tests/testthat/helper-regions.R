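# Small in-code region builders and an independent shortest-path oracle.

# A minimal valid region from vectors; edges given as data.frame or NULL.
tiny_region <- function(pop, edges = NULL, fixed = rep(0L, length(pop)),
                        urban = rep(0.8, length(pop)),
                        machine_years = fixed * 2,
                        exams = rep(0L, length(pop)),
                        ids = sprintf("t%02d", seq_along(pop))) {
  screening_region(
    data.frame(id = ids, name = toupper(ids),
               eligible_population = as.integer(pop),
               urban_fraction = urban,
               fixed_units = as.integer(fixed),
               machine_years_observed = machine_years,
               exams_realized = as.integer(exams),
               stringsAsFactors = FALSE),
    edges)
}

# line graph t01 - t02 - ... with unit-ish distances
line_edges <- function(n, dist = rep(10, n - 1)) {
  ids <- sprintf("t%02d", seq_len(n))
  data.frame(id_a = ids[-n], id_b = ids[-1], distance_km = dist,
             stringsAsFactors = FALSE)
}

# Independent oracle: minimum distance over ALL simple paths, by exhaustive
# depth-first enumeration of the edge list. Only usable on tiny graphs.
brute_force_distance <- function(edges, ids, from, to) {
  if (from == to) return(0)
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    a <- edges$id_a[k]; b <- edges$id_b[k]; d <- edges$distance_km[k]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, d = d))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, d = d))
  }
  best <- Inf
  walk <- function(node, seen, acc) {
    if (acc >= best) return()
    if (node == to) { best <<- acc; return() }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      if (!(nb$to[k] %in% seen)) {
        walk(nb$to[k], c(seen, nb$to[k]), acc + nb$d[k])
      }
    }
  }
  walk(from, from, 0)
  best
}

# random connected graph on n nodes: random tree plus a few extra edges
random_connected_edges <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  a <- integer(0); b <- integer(0)
  if (n > 1) {
    for (k in 2:n) {
      a <- c(a, k); b <- c(b, sample.int(k - 1L, 1L))
    }
    for (i in seq_len(max(0L, n %/% 2))) {
      cand <- sample.int(n, 2L)
      key_new <- paste(min(cand), max(cand))
      keys <- paste(pmin(a, b), pmax(a, b))
      if (!(key_new %in% keys)) { a <- c(a, cand[1L]); b <- c(b, cand[2L]) }
    }
  }
  data.frame(id_a = ids[a], id_b = ids[b],
             distance_km = round(runif(length(a), 1, 50), 1),
             stringsAsFactors = FALSE)
}

serrana <- function() load_region_fixture("serrana_2015_2016")
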