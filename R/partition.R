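#' Cut-ratio score of a candidate cluster
#'
#' The greedy partitioner scores a candidate cluster by
#' \deqn{(E_{out}/E_{in}) \cdot (1/d), \qquad d = 2E_{in}/(|V|(|V|-1)),}
#' where \eqn{E_{in}} is the number of edges inside the cluster,
#' \eqn{E_{out}} the number of edges from the cluster to the rest of its
#' connected component, and \eqn{d} the cluster's edge density.  Lower is
#' better: the score balances the edges that must be cut against the edges
#' (weighted by density) that are kept.  A score of 0 means the cluster is a
#' free-standing component; a cluster with no internal edge (an isolated
#' node) gets the sentinel `Inf`, so singletons are only ever emitted when a
#' component has shrunk to a single node.
#'
#' @inheritParams graph_complement
#' @param cluster Character vector of node identifiers (non-empty).
#' @param component Nodes of the connected component containing `cluster`;
#'   derived from the graph when `NULL`.
#' @return A one-row tibble with columns `n_nodes`, `e_in`, `e_out`,
#'   `density` and `score`.
#' @examples
#' # triangle with two outgoing edges: (2/3) * 1
#' g <- ppi_graph(cbind(c("a", "a", "b", "a", "b"), c("b", "c", "c", "x", "y")))
#' cut_ratio(g, c("a", "b", "c"))
#' @export
cut_ratio <- function(g, cluster, component = NULL) {
  g <- as_ppi_graph(g)
  cluster <- unique(as.character(cluster))
  if (length(cluster) == 0) abort("`cluster` must be non-empty.")
  check_nodes(g, cluster, "cluster")
  if (is.null(component)) {
    comps <- graph_components(g)
    component <- comps[[which(map_lgl(comps, function(x) cluster[1] %in% x))]]
  }
  if (!all(cluster %in% component)) {
    abort("`cluster` must be a subset of `component`.")
  }
  cluster_stats(g, cluster)
}

# hot-path version: no validation, `g` is the residual graph and `cluster`
# lies inside one of its connected components.
cluster_stats <- function(g, cluster) {
  n <- length(cluster)
  e_in <- igraph::ecount(induced(g, cluster))
  e_out <- sum(igraph::degree(g, cluster)) - 2L * e_in
  density <- if (n >= 2) 2 * e_in / (n * (n - 1)) else NA_real_
  score <- if (e_in == 0) Inf else (e_out / e_in) * (1 / density)
  tibble(
    n_nodes = n, e_in = as.integer(e_in), e_out = as.integer(e_out),
    density = density, score = score
  )
}

# (candidate, stats) ordering used everywhere: smaller score first, then
# larger cluster, then lexicographically smallest member set.
better_candidate <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$stats$score != b$stats$score) {
    # NB: Inf == Inf, so ties (incl. two sentinels) fall through
    return(a$stats$score < b$stats$score)
  }
  if (length(a$cluster) != length(b$cluster)) {
    return(length(a$cluster) > length(b$cluster))
  }
  lex_before(a$cluster, b$cluster)
}

#' Best biclique-spanned cluster in a node's second neighborhood
#'
#' The candidate-generation step of the partitioner.  For a node `v`, the
#' second neighborhood `N2(v)` is extracted and the complement of its
#' induced subgraph inspected.  If that complement is disconnected, `N2(v)`
#' already induces a biclique-spanned subgraph and is the candidate.
#' Otherwise a node cut of the complement is removed from the candidate
#' (removing a vertex cut of the complement disconnects it, leaving a
#' biclique-spanned remainder):
#'
#' * complement has at most `exact_cut_threshold` nodes: all minimum-size
#'   separators are enumerated exactly (max-flow based) and each resulting
#'   candidate scored;
#' * otherwise, if the complement has articulation points each provides a
#'   size-1 cut;
#' * otherwise the neighbors of each minimum-degree node of the complement
#'   form a heuristic cut (removing them isolates that node).
#'
#' Among the scored variants the best candidate (smallest cut-ratio score,
#' then largest, then lexicographically smallest) is returned.  Cut nodes
#' are *not* discarded from the graph: they stay behind for later
#' iterations of the partitioner.
#'
#' @inheritParams graph_complement
#' @param node Node identifier.
#' @param component Nodes of the connected component containing `node`;
#'   derived when `NULL`.
#' @param exact_cut_threshold Largest complement size on which the exact
#'   minimum-cut enumeration is used (default 20).
#' @return A list with elements `cluster` (sorted character vector) and
#'   `stats` (the [cut_ratio()] row).
#' @examples
#' g <- ppi_graph(cbind(letters[1:5], letters[c(2:5, 1)]))  # 5-cycle
#' candidate_cluster(g, "a")$stats$score                    # 1.5
#' @export
candidate_cluster <- function(g, node, component = NULL, exact_cut_threshold = 20) {
  g <- as_ppi_graph(g)
  if (length(node) != 1) abort("`node` must be a single identifier.")
  check_nodes(g, node, "node")
  if (is.null(component)) {
    comps <- graph_components(g)
    component <- comps[[which(map_lgl(comps, function(x) node %in% x))]]
  } else if (!node %in% component) {
    abort("`node` must belong to `component`.")
  }
  cnp(g, node, exact_cut_threshold)
}

cnp <- function(g, node, exact_cut_threshold = 20, memo = NULL) {
  n2 <- igraph::ego(g, order = 2, nodes = node)[[1]]$name
  if (!is.null(memo)) {
    # nodes sharing a second neighborhood share the candidate; on dense
    # components N2 is often the whole component for every node
    key <- paste(lex_sort(n2), collapse = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
  }
  res <- cnp_from_n2(g, n2, exact_cut_threshold)
  if (!is.null(memo)) memo[[key]] <- res
  res
}

cnp_from_n2 <- function(g, n2, exact_cut_threshold = 20) {
  if (length(n2) == 1) {
    return(list(cluster = n2, stats = cluster_stats(g, n2)))
  }
  hc <- igraph::complementer(induced(g, n2))
  if (igraph::count_components(hc) >= 2) {
    cl <- lex_sort(n2)
    return(list(cluster = cl, stats = cluster_stats(g, cl)))
  }
  cuts <- complement_cuts(hc, exact_cut_threshold)
  best <- NULL
  for (cut in cuts) {
    cl <- lex_sort(setdiff(n2, cut))
    cand <- list(cluster = cl, stats = cluster_stats(g, cl))
    if (better_candidate(cand, best)) best <- cand
  }
  best
}

# candidate node cuts of a connected complement graph `hc`
complement_cuts <- function(hc, exact_cut_threshold) {
  if (igraph::vcount(hc) <= exact_cut_threshold) {
    return(lapply(igraph::min_separators(hc), function(s) s$name))
  }
  arts <- igraph::articulation_points(hc)
  if (length(arts) > 0) {
    return(as.list(igraph::V(hc)$name[as.integer(arts)]))
  }
  deg <- igraph::degree(hc)
  mins <- names(deg)[deg == min(deg)]
  lapply(mins, function(x) igraph::neighbors(hc, x)$name)
}

#' Partition a PPI network into biclique-spanned clusters
#'
#' The package's main algorithm: a parameter-free greedy approximation to
#' the optimal *coherent partition* -- the partition of the node set into
#' biclique-spanned blocks that removes the fewest edges (an NP-hard
#' problem).  Per iteration, each surviving connected component is scanned:
#' every node proposes its best second-neighborhood candidate (see
#' [candidate_cluster()]), the minimum-score candidate is fixed as a
#' cluster, its boundary edges join the edge cut, and its nodes leave the
#' working graph.  Components are then recomputed and the process repeats
#' until no nodes remain.
#'
#' All tie-breaking is lexicographic, so the result is deterministic --
#' identical inputs give identical partitions with no seed involved.
#'
#' @inheritParams graph_complement
#' @inheritParams candidate_cluster
#' @return An object of class `coherent_partition`: a list with
#'   * `clusters`: list of sorted character vectors, ordered by decreasing
#'     size then first member (every cluster induces a biclique-spanned
#'     subgraph; singletons allowed);
#'   * `edge_cut`: tibble (`from`, `to`) of the removed edges -- exactly the
#'     input edges whose endpoints ended up in different clusters;
#'   * `graph`: the input graph.
#'   Methods: [print()], [tidy()], [glance()], [autoplot()].
#' @examples
#' net <- plant_network(fixture_plant_specs()[[1]], noise_edges = 0, seed = 1)
#' cp <- coherent_partition(net$graph)
#' glance(cp)
#' @export
coherent_partition <- function(g, exact_cut_threshold = 20) {
  g <- as_ppi_graph(g)
  residual <- g
  clusters <- list()
  cut_from <- character(0)
  cut_to <- character(0)

  while (igraph::vcount(residual) > 0) {
    comps <- graph_components(residual)
    picked <- list()
    for (comp in comps) {
      if (length(comp) == 1) {
        picked[[length(picked) + 1]] <- comp
        next
      }
      best <- NULL
      memo <- new.env(parent = emptyenv())
      for (v in comp) {
        cand <- cnp(residual, v, exact_cut_threshold, memo)
        if (better_candidate(cand, best)) best <- cand
      }
      cl <- best$cluster
      if (length(cl) < length(comp)) {
        inc <- unique(unlist(igraph::incident_edges(residual, cl)))
        if (length(inc) > 0) {
          en <- igraph::ends(residual, inc)
          cross <- xor(en[, 1] %in% cl, en[, 2] %in% cl)
          en <- en[cross, , drop = FALSE]
          cut_from <- c(cut_from, pmin(en[, 1], en[, 2]))
          cut_to <- c(cut_to, pmax(en[, 1], en[, 2]))
        }
      }
      picked[[length(picked) + 1]] <- cl
    }
    clusters <- c(clusters, picked)
    residual <- igraph::delete_vertices(residual, unlist(picked))
  }

  clusters <- clusters[order(
    -lengths(clusters), map_chr(clusters, function(x) x[1] %||% ""),
    method = "radix"
  )]
  edge_cut <- tibble(from = cut_from, to = cut_to) |>
    arrange(.data$from, .data$to)
  structure(
    list(
      clusters = clusters, edge_cut = edge_cut, graph = g,
      exact_cut_threshold = exact_cut_threshold
    ),
    class = "coherent_partition"
  )
}

#' Check that a partition is a valid coherent partition of a graph
#'
#' Verifies every structural invariant of a partition against a graph:
#' clusters are disjoint, cover all nodes, each induces a biclique-spanned
#' subgraph (singletons count), and -- when an edge cut is supplied -- the
#' cut is exactly the set of edges crossing clusters.  Failures are
#' reported via messages and returned in the `"reasons"` attribute rather
#' than as errors, so the function can be used as a property check.
#'
#' @inheritParams graph_complement
#' @param partition A `coherent_partition`, or a list with elements
#'   `clusters` (list of character vectors) and optionally `edge_cut`
#'   (data frame with columns `from`, `to`), or a bare list of clusters.
#' @return `TRUE` or `FALSE` (with attribute `"reasons"`).
#' @export
verify_partition <- function(g, partition) {
  g <- as_ppi_graph(g)
  if (inherits(partition, "coherent_partition") ||
      (is.list(partition) && !is.null(partition$clusters))) {
    clusters <- partition$clusters
    edge_cut <- partition$edge_cut
  } else {
    clusters <- partition
    edge_cut <- NULL
  }
  reasons <- character(0)
  all_nodes <- unlist(clusters)
  if (any(duplicated(all_nodes))) {
    reasons <- c(reasons, "clusters overlap")
  }
  if (!setequal(all_nodes, node_names(g))) {
    reasons <- c(reasons, "clusters do not cover the node set exactly")
  }
  ok_nodes <- all(all_nodes %in% node_names(g))
  if (ok_nodes && !any(duplicated(all_nodes))) {
    bs <- map_lgl(clusters, function(cl) {
      length(cl) == 1 || is_biclique_spanned(induced(g, cl))
    })
    if (!all(bs)) {
      reasons <- c(reasons, sprintf(
        "%d cluster(s) are not biclique spanned", sum(!bs)
      ))
    }
  }
  if (!is.null(edge_cut)) {
    expected <- crossing_edges(g, clusters)
    got <- paste(pmin(edge_cut$from, edge_cut$to),
                 pmax(edge_cut$from, edge_cut$to), sep = "\r")
    if (!setequal(got, expected) || anyDuplicated(got) > 0) {
      reasons <- c(reasons, "edge cut is not exactly the set of inter-cluster edges")
    }
  }
  if (length(reasons) > 0) {
    inform(paste0("Invalid partition: ", paste(reasons, collapse = "; ")))
    return(structure(FALSE, reasons = reasons))
  }
  structure(TRUE, reasons = character(0))
}

# keys "a\rb" of edges of g whose endpoints lie in different clusters
crossing_edges <- function(g, clusters) {
  if (igraph::ecount(g) == 0) return(character(0))
  memb <- integer(igraph::vcount(g))
  names(memb) <- node_names(g)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  en <- igraph::ends(g, igraph::E(g))
  cross <- memb[en[, 1]] != memb[en[, 2]]
  paste(pmin(en[cross, 1], en[cross, 2]),
        pmax(en[cross, 1], en[cross, 2]), sep = "\r")
}

#' @export
print.coherent_partition <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf(
    "Coherent partition: %d nodes, %d edges -> %d clusters (%d singletons), %d edges cut\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(x$clusters), sum(sizes == 1), nrow(x$edge_cut)
  ))
  if (length(sizes) > 0) {
    cat(sprintf(
      "Cluster sizes: max %d, median %s\n", max(sizes), format(stats::median(sizes))
    ))
  }
  invisible(x)
}

#' Per-cluster summary of a coherent partition
#'
#' @param x A `coherent_partition`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster` id, `size`,
#'   `members` (list column), `e_in`, `e_out` (against the full input
#'   graph), `density` and cut-ratio `score`.
#' @exportS3Method generics::tidy
tidy.coherent_partition <- function(x, ...) {
  stats <- bind_rows(lapply(x$clusters, function(cl) cluster_stats(x$graph, cl)))
  tibble(
    cluster = seq_along(x$clusters),
    size = lengths(x$clusters),
    members = x$clusters
  ) |>
    dplyr::bind_cols(select(stats, "e_in", "e_out", "density", "score"))
}

#' One-row summary of a coherent partition
#'
#' @inheritParams tidy.coherent_partition
#' @return A one-row tibble: node/edge counts, cluster counts, edge-cut
#'   size and fraction, and Newman modularity of the partition (`NA` for an
#'   edgeless graph).
#' @exportS3Method generics::glance
glance.coherent_partition <- function(x, ...) {
  m <- igraph::ecount(x$graph)
  sizes <- lengths(x$clusters)
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = m,
    n_clusters = length(x$clusters),
    n_singletons = sum(sizes == 1),
    max_cluster_size = if (length(sizes) > 0) max(sizes) else 0L,
    n_edge_cut = nrow(x$edge_cut),
    prop_edges_cut = if (m > 0) nrow(x$edge_cut) / m else NA_real_,
    modularity = if (m > 0) cluster_modularity(x$graph, x$clusters) else NA_real_
  )
}

#' Cluster-size distribution plot
#'
#' @param object A `coherent_partition`.
#' @param ... Unused.
#' @return A ggplot: number of clusters at each size.
#' @exportS3Method ggplot2::autoplot
autoplot.coherent_partition <- function(object, ...) {
  tibble(size = lengths(object$clusters)) |>
    count(.data$size) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$size, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Cluster size (proteins)", y = "Number of clusters",
      title = "Predicted complex size distribution"
    ) +
    ggplot2::theme_minimal()
}
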