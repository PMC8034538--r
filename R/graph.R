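#' Build a simple undirected PPI graph from an edge list
#'
#' Constructs the network container used throughout the package: a simple
#' (no self-loops, no multi-edges) undirected [igraph][igraph::igraph-package]
#' graph whose vertices are named by protein identifier strings.  Vertices
#' are stored in lexicographic (C-collation) order, which makes every
#' downstream iteration order, and hence the whole partitioning pipeline,
#' deterministic without a seed.
#'
#' Duplicate edges (in either orientation) and self-loops are dropped
#' silently apart from an informational message, since both are common in
#' raw PPI exports.
#'
#' @param edges A data frame whose first two columns hold the interacting
#'   protein identifiers (coerced to character), or a two-column character
#'   matrix.  Additional columns (e.g. confidence weights) are ignored.
#' @param nodes Optional character vector of additional isolated nodes to
#'   include beyond the edge endpoints.
#'
#' @return An undirected, simple, named `igraph` object.
#' @examples
#' g <- ppi_graph(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' igraph::vcount(g)
#' @seealso [read_ppi_network()] to build one from a file.
#' @export
ppi_graph <- function(edges, nodes = character()) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges)) {
    abort("`edges` must be a data frame or matrix with at least two columns.")
  }
  if (nrow(edges) > 0 && ncol(edges) < 2) {
    abort("`edges` must have at least two columns (interactor A, interactor B).")
  }
  from <- character(0)
  to <- character(0)
  if (nrow(edges) > 0) {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    if (anyNA(from) || anyNA(to) || any(from == "") || any(to == "")) {
      abort("Edge endpoints must be non-missing, non-empty strings.")
    }
  }
  loops <- from == to
  if (any(loops)) {
    inform(sprintf("Dropped %d self-loop(s).", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  # canonical unordered orientation, then dedup
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    inform(sprintf("Dropped %d duplicate edge(s).", sum(dup)))
    a <- a[!dup]
    b <- b[!dup]
  }
  vs <- lex_sort(unique(c(a, b, as.character(nodes))))
  g <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vs)
  if (length(a) > 0) {
    g <- igraph::add_edges(g, rbind(a, b))
  }
  g
}

#' Coerce to a simple undirected named graph
#'
#' @param x An `igraph` object (checked), a data frame / matrix edge list
#'   (passed to [ppi_graph()]), or a `planted_network` (its graph is used).
#' @return An undirected, simple, named `igraph` object.
#' @export
as_ppi_graph <- function(x) {
  if (inherits(x, "planted_network")) {
    return(x$graph)
  }
  if (igraph::is_igraph(x)) {
    if (igraph::is_directed(x)) abort("Graph must be undirected.")
    if (!igraph::is_simple(x)) abort("Graph must be simple (no loops or multi-edges).")
    if (igraph::vcount(x) > 0 && is.null(igraph::V(x)$name)) {
      abort("Graph vertices must be named.")
    }
    return(x)
  }
  ppi_graph(x)
}

node_names <- function(g) {
  if (igraph::vcount(g) == 0) character(0) else igraph::V(g)$name
}

check_nodes <- function(g, nodes, arg = "nodes") {
  missing <- setdiff(nodes, node_names(g))
  if (length(missing) > 0) {
    abort(sprintf(
      "Unknown node identifier(s) in `%s`: %s", arg,
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

induced <- function(g, nodes) {
  igraph::induced_subgraph(g, nodes)
}

#' Complement of a simple graph
#'
#' Returns the graph on the same node set in which two distinct nodes are
#' adjacent exactly when they are not adjacent in the input.  The complement
#' is central to this package because a graph is biclique spanned if and
#' only if its complement is disconnected (see [is_biclique_spanned()]).
#'
#' @param g A simple undirected named graph (or edge-list data frame).
#' @return An `igraph` object of the same class of graphs.
#' @examples
#' igraph::ecount(graph_complement(ppi_graph(cbind(c("a", "b"), c("b", "c")))))
#' @export
graph_complement <- function(g) {
  g <- as_ppi_graph(g)
  igraph::complementer(g)
}

#' Second neighborhood of a node
#'
#' All nodes at shortest-path distance at most 2 from `node`, including the
#' node itself.  Any biclique-spanned subgraph containing a node lies inside
#' its second neighborhood (such graphs have diameter at most 2), which is
#' why the partitioning algorithm searches there.
#'
#' @inheritParams graph_complement
#' @param node A single node identifier present in the graph.
#' @return Sorted character vector of node identifiers.
#' @examples
#' g <- ppi_graph(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")))
#' second_neighborhood(g, "a")
#' @export
second_neighborhood <- function(g, node) {
  g <- as_ppi_graph(g)
  if (length(node) != 1) abort("`node` must be a single identifier.")
  check_nodes(g, node, "node")
  nb <- igraph::ego(g, order = 2, nodes = node)[[1]]
  lex_sort(nb$name)
}

#' Connected components of a graph
#'
#' @inheritParams graph_complement
#' @return A list of sorted character vectors (one per component), ordered
#'   by their lexicographically smallest member; the empty graph yields an
#'   empty list.
#' @export
graph_components <- function(g) {
  g <- as_ppi_graph(g)
  if (igraph::vcount(g) == 0) return(list())
  memb <- igraph::components(g)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(unname(comps), lex_sort)
  comps[order(map_chr(comps, 1), method = "radix")]
}

#' Is a graph biclique spanned?
#'
#' A graph is *biclique spanned* if its nodes can be split into two
#' non-empty parts with every cross-part edge present (within-part edges
#' unrestricted).  The class covers stars, complete bipartite graphs and
#' cliques -- the full density continuum observed in curated protein
#' complexes.  Equivalently, and this is how it is computed here, a graph
#' is biclique spanned iff its complement is disconnected.
#'
#' A single-node graph is treated as (degenerately) biclique spanned, so
#' that stranded singleton clusters remain representable; the bipartition
#' definition itself requires at least two nodes.
#'
#' @inheritParams graph_complement
#' @return `TRUE` or `FALSE`.  The empty graph is an error.
#' @examples
#' is_biclique_spanned(make_complex("star", 4))   # stars qualify
#' is_biclique_spanned(ppi_graph(cbind(letters[1:5], letters[c(2:5, 1)]))) # C5: no
#' @export
is_biclique_spanned <- function(g) {
  g <- as_ppi_graph(g)
  n <- igraph::vcount(g)
  if (n == 0) abort("The empty graph is neither biclique spanned nor not; supply >= 1 node.")
  if (n == 1) return(TRUE)
  igraph::count_components(igraph::complementer(g)) >= 2
}

#' Articulation points of a connected graph
#'
#' Nodes whose removal disconnects the graph.  Used by the partitioner as a
#' fast path: an articulation point of the complement of a second
#' neighborhood is a size-1 node cut.
#'
#' @inheritParams graph_complement
#' @return Sorted character vector (possibly empty).
#' @export
articulation_nodes <- function(g) {
  g <- as_ppi_graph(g)
  if (igraph::vcount(g) == 0 || !igraph::is_connected(g)) {
    abort("`g` must be a non-empty connected graph.")
  }
  pts <- igraph::articulation_points(g)
  lex_sort(igraph::V(g)$name[as.integer(pts)])
}

#' Minimum node cut of a connected graph
#'
#' A smallest set of nodes whose removal disconnects the graph, computed via
#' max-flow-based vertex connectivity.  Complete graphs (and graphs with
#' fewer than three nodes) have no vertex cut and raise an error.  Any
#' minimum cut is equally valid; for reproducibility the lexicographically
#' smallest of the minimum separators found is returned.
#'
#' @inheritParams graph_complement
#' @return Sorted character vector of cut nodes.
#' @examples
#' min_node_cut(ppi_graph(cbind(c("a", "b"), c("b", "c"))))  # "b"
#' @export
min_node_cut <- function(g) {
  g <- as_ppi_graph(g)
  n <- igraph::vcount(g)
  if (n < 3) abort("A vertex cut requires at least 3 nodes.")
  if (!igraph::is_connected(g)) abort("`g` must be connected.")
  if (igraph::ecount(g) == n * (n - 1) / 2) {
    abort("Complete graphs have no vertex cut.")
  }
  seps <- igraph::min_separators(g)
  sets <- lapply(seps, function(s) lex_sort(s$name))
  best <- sets[[1]]
  for (s in sets[-1]) if (lex_before(s, best)) best <- s
  best
}

#' Diameter of an induced subgraph
#'
#' Maximum pairwise shortest-path distance within the subgraph induced by
#' `nodes`.  Every biclique-spanned graph on two or more nodes has induced
#' diameter at most 2, which the partitioner's output must respect.
#'
#' @inheritParams graph_complement
#' @param nodes Node identifiers inducing a connected subgraph (a singleton
#'   has diameter 0).
#' @return Integer diameter; disconnected induced subgraphs are an error.
#' @export
induced_diameter <- function(g, nodes) {
  g <- as_ppi_graph(g)
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0) abort("`nodes` must be non-empty.")
  check_nodes(g, nodes)
  if (length(nodes) == 1) return(0L)
  d <- igraph::distances(induced(g, nodes))
  if (any(is.infinite(d))) abort("`nodes` induce a disconnected subgraph.")
  as.integer(max(d))
}
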