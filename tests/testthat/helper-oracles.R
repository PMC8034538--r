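# Independent brute-force oracles and small graph builders used across the
# suite.  Oracles deliberately avoid the code paths they check: the
# biclique-spanned oracle enumerates bipartitions (the primal definition),
# the cut oracle enumerates node subsets, the matching oracle searches
# assignments recursively.

edgelist <- function(...) {
  m <- matrix(c(..., character(0)), ncol = 2, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

path_graph <- function(v) ppi_graph(cbind(v[-length(v)], v[-1]))
cycle_graph <- function(v) ppi_graph(cbind(v, v[c(2:length(v), 1)]))
complete_graph <- function(v) ppi_graph(t(combn(v, 2)))
star_graph <- function(center, leaves) ppi_graph(cbind(center, leaves))

c5 <- function() cycle_graph(letters[1:5])

two_k4_bridge <- function() {
  ppi_graph(rbind(
    t(combn(c("a", "b", "c", "d"), 2)),
    t(combn(c("e", "f", "g", "h"), 2)),
    c("d", "e")
  ))
}

rand_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

rand_connected_gnp <- function(n, p) {
  repeat {
    g <- rand_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

# primal definition: exists a bipartition (V1, V2), both non-empty, with
# every cross edge present
brute_biclique_spanned <- function(g) {
  n <- igraph::vcount(g)
  if (n == 1) return(TRUE)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  bits <- 2^(0:(n - 2))
  for (mask in 1:(2^(n - 1) - 1)) {
    # node 1 always in V1; mask selects V2 among nodes 2..n
    v2 <- c(FALSE, bitwAnd(mask, bits) > 0)
    if (all(A[!v2, v2, drop = FALSE] == 1)) return(TRUE)
  }
  FALSE
}

# smallest k such that removing some k-subset of nodes disconnects g
brute_min_cut_size <- function(g) {
  n <- igraph::vcount(g)
  vs <- igraph::V(g)$name
  for (k in 1:(n - 2)) {
    subs <- combn(vs, k)
    for (i in seq_len(ncol(subs))) {
      h <- igraph::delete_vertices(g, subs[, i])
      if (igraph::vcount(h) >= 2 && !igraph::is_connected(h)) return(k)
    }
  }
  NA_integer_
}

# maximum-weight bipartite matching by exhaustive assignment search
brute_matching_weight <- function(w) {
  n <- nrow(w)
  m <- ncol(w)
  rec <- function(i, used) {
    if (i > n) return(0)
    best <- rec(i + 1, used)
    for (j in seq_len(m)) {
      if (!used[j] && w[i, j] > 0) {
        used[j] <- TRUE
        best <- max(best, w[i, j] + rec(i + 1, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1, logical(m))
}

rand_complex_set <- function(n_cx, universe, sizes = 2:5) {
  lapply(seq_len(n_cx), function(i) sample(universe, sample(sizes, 1)))
}

map_keys <- function(clusters) vapply(clusters, paste, "", collapse = " ")

edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  en <- igraph::as_edgelist(g)
  sort(paste(pmin(en[, 1], en[, 2]), pmax(en[, 1], en[, 2])))
}

# intra-cluster edge keys + edge-cut keys of a partition
partition_edge_keys <- function(p) {
  intra <- unlist(lapply(p$clusters, function(cl) {
    if (length(cl) < 2) return(character(0))
    edge_keys(igraph::induced_subgraph(p$graph, cl))
  }))
  cut <- if (nrow(p$edge_cut) > 0) paste(p$edge_cut$from, p$edge_cut$to) else character(0)
  sort(c(intra, cut))
}
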