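#' Coerce to a list of complexes
#'
#' A *complex set* is a plain list of non-empty character vectors -- gold
#' standard complexes or predicted clusters.  Gold standards may overlap;
#' the partitioner's own output never does.  Duplicate members within a
#' complex are removed and members are sorted.
#'
#' @param x A list of character vectors, a `coherent_partition` (its
#'   clusters are taken), or a single character vector (one complex).
#' @return A list of sorted, deduplicated character vectors.
#' @export
as_complex_list <- function(x) {
  if (inherits(x, "coherent_partition")) x <- x$clusters
  if (inherits(x, "planted_network")) x <- x$complexes
  if (is.character(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0) {
    abort("Expected a non-empty list of complexes (character vectors).")
  }
  out <- lapply(x, function(cx) {
    cx <- unique(as.character(cx))
    if (length(cx) == 0 || anyNA(cx)) abort("Complexes must be non-empty and free of NA.")
    lex_sort(cx)
  })
  unname(out)
}

#' Contingency table between gold complexes and predicted clusters
#'
#' Entry `t[i, j]` counts the proteins shared by gold complex `i` and
#' predicted cluster `j`.  Because complex sets may overlap internally, the
#' marginal sums of the table need not equal the complex or cluster sizes;
#' both are therefore carried separately.
#'
#' @param gold,pred Complex sets (see [as_complex_list()]); `gold` indexes
#'   rows, `pred` columns.
#' @return An integer matrix of class `contingency_table` with attributes
#'   `row_sizes` (complex sizes \eqn{N_i}) and `col_sizes` (cluster sizes
#'   \eqn{P_j}).
#' @examples
#' contingency_table(list(c("a", "b", "c", "d")), list(c("a", "b"), c("c", "d")))
#' @export
contingency_table <- function(gold, pred) {
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  t <- matrix(0L, nrow = length(gold), ncol = length(pred))
  for (i in seq_along(gold)) {
    for (j in seq_along(pred)) {
      t[i, j] <- length(intersect(gold[[i]], pred[[j]]))
    }
  }
  structure(
    t,
    row_sizes = lengths(gold), col_sizes = lengths(pred),
    class = c("contingency_table", class(t))
  )
}

as_contingency <- function(gold, pred) {
  if (inherits(gold, "contingency_table") && missing(pred)) gold
  else contingency_table(gold, pred)
}

#' Sensitivity, positive predictive value and accuracy
#'
#' Clustering-wise contingency measures: sensitivity
#' \eqn{SN = \sum_i \max_j t_{ij} / \sum_i N_i}, positive predictive value
#' \eqn{PPV = \sum_j \max_i t_{ij} / \sum_j\sum_i t_{ij}}, and accuracy
#' \eqn{ACC = \sqrt{SN \cdot PPV}} (geometric mean).  An all-zero table
#' (no shared protein anywhere) yields `(0, 0, 0)` by the package's
#' worst-score convention.
#'
#' @param tab A `contingency_table` from [contingency_table()].
#' @return A one-row tibble with columns `sn`, `ppv`, `acc`.
#' @export
sn_ppv_acc <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  sn <- sum(apply(tab, 1, max)) / sum(attr(tab, "row_sizes"))
  tot <- sum(tab)
  ppv <- if (tot == 0) 0 else sum(apply(tab, 2, max)) / tot
  tibble(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Separation between complexes and clusters
#'
#' For each complex/cluster pair, \eqn{sep_{ij} = (t_{ij}/t_{\cdot j})
#' (t_{ij}/t_{i\cdot})} multiplies the proportion of a cluster's covered
#' proteins found in the complex by the proportion of the complex's covered
#' proteins found in the cluster.  Complex-wise separation averages
#' \eqn{\sum_j sep_{ij}} over complexes, cluster-wise over clusters, and
#' the reported separation is the geometric mean of the two.  Pairs on
#' zero marginals contribute 0 rather than NaN.
#'
#' @inheritParams sn_ppv_acc
#' @return A single number in \[0, 1\] for disjoint complex sets.
#' @export
separation <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  rs <- rowSums(tab)
  cs <- colSums(tab)
  denom <- outer(rs, cs)
  sep <- matrix(0, nrow(tab), ncol(tab))
  pos <- denom > 0
  sep[pos] <- (tab[pos]^2) / denom[pos]
  complex_wise <- sum(sep) / nrow(tab)
  cluster_wise <- sum(sep) / ncol(tab)
  sqrt(complex_wise * cluster_wise)
}

#' Overlap score between two protein sets
#'
#' \eqn{\omega(A, B) = |A \cap B|^2 / (|A| |B|)}: 1 for identical sets, 0
#' for disjoint ones.  This single quantity backs the fraction-match
#' threshold, the maximum-matching-ratio edge weights and the neighborhood
#' affinity (NA) score -- all three are the same formula.
#'
#' @param a,b Non-empty character vectors.
#' @return A number in \[0, 1\].
#' @export
overlap_score <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) abort("`a` and `b` must be non-empty.")
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# |gold| x |pred| matrix of overlap scores
overlap_matrix <- function(gold, pred) {
  m <- matrix(0, length(gold), length(pred))
  for (i in seq_along(gold)) {
    for (j in seq_along(pred)) {
      m[i, j] <- overlap_score(gold[[i]], pred[[j]])
    }
  }
  m
}

#' Fraction of complexes matched above an overlap threshold
#'
#' The fraction-match (FRM) measure: the proportion of gold complexes for
#' which some predicted cluster exceeds the overlap-score threshold
#' (strictly; default 0.25, the conventional value).  Set
#' `count = "pred"` to instead report the proportion of predicted clusters
#' matched by some gold complex.
#'
#' @inheritParams contingency_table
#' @param threshold Overlap-score threshold in \[0, 1\]; a match requires a
#'   score strictly greater.
#' @param count Count matched gold complexes (default) or matched clusters.
#' @return A number in \[0, 1\].
#' @export
fraction_match <- function(gold, pred, threshold = 0.25, count = c("gold", "pred")) {
  count <- match.arg(count)
  if (threshold < 0 || threshold > 1) abort("`threshold` must lie in [0, 1].")
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  w <- overlap_matrix(gold, pred)
  if (count == "gold") {
    mean(apply(w, 1, function(x) any(x > threshold)))
  } else {
    mean(apply(w, 2, function(x) any(x > threshold)))
  }
}

#' Maximum matching ratio
#'
#' Builds the bipartite graph with gold complexes on one side, predicted
#' clusters on the other and overlap scores as edge weights (zero-weight
#' pairs omitted), finds a maximum-weight matching, and divides its total
#' weight by the number of gold complexes.  Unlike the contingency-based
#' measures, each cluster can pay towards at most one complex, so MMR
#' penalizes both fragmented and duplicated predictions.
#'
#' @inheritParams contingency_table
#' @return A number in \[0, 1\].
#' @export
max_matching_ratio <- function(gold, pred) {
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  w <- overlap_matrix(gold, pred)
  matching_weight(w) / length(gold)
}

# total weight of a maximum-weight bipartite matching of a weight matrix
matching_weight <- function(w) {
  idx <- which(w > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  g <- bipartite_pair_graph(nrow(w), ncol(w), idx)
  m <- igraph::max_bipartite_match(g, weights = w[idx])
  matched <- m$matching[seq_len(nrow(w))]
  keep <- !is.na(matched)
  i <- seq_len(nrow(w))[keep]
  j <- as.integer(sub("^p", "", matched[keep]))
  sum(w[cbind(i, j)])
}

# bipartite graph on rows g1..gn (type FALSE) and columns p1..pm (type TRUE)
bipartite_pair_graph <- function(n, m, idx) {
  g <- igraph::make_empty_graph(n + m, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = c(paste0("g", seq_len(n)),
                                                    paste0("p", seq_len(m))))
  g <- igraph::set_vertex_attr(g, "type", value = rep(c(FALSE, TRUE), c(n, m)))
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, rbind(paste0("g", idx[, 1]), paste0("p", idx[, 2])))
  }
  g
}

#' Jaccard-based precision, recall and F-measure
#'
#' A predicted cluster matches a reference complex when their Jaccard
#' similarity exceeds 0.5 (strictly).  Precision is the fraction of
#' predicted clusters matching at least one complex, recall the fraction of
#' complexes matched by at least one cluster, and the F-measure their
#' harmonic mean (0 when both are 0).
#'
#' @inheritParams contingency_table
#' @return A one-row tibble: `precision`, `recall`, `f_measure`.
#' @export
jaccard_prf <- function(gold, pred) {
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  jac <- matrix(0, length(gold), length(pred))
  for (i in seq_along(gold)) {
    for (j in seq_along(pred)) {
      inter <- length(intersect(gold[[i]], pred[[j]]))
      jac[i, j] <- inter / (length(gold[[i]]) + length(pred[[j]]) - inter)
    }
  }
  match <- jac > 0.5
  precision <- mean(apply(match, 2, any))
  recall <- mean(apply(match, 1, any))
  tibble(
    precision = precision, recall = recall,
    f_measure = harmonic_or_zero(precision, recall)
  )
}

harmonic_or_zero <- function(p, r) {
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Neighborhood-affinity precision+, recall+ and F-measure+
#'
#' The matching-restricted counterparts of precision and recall: pairs
#' whose neighborhood-affinity score (the [overlap_score()]) is at least
#' `theta` (and positive) are eligible edges of a bipartite graph on which
#' a maximum-cardinality matching is computed.  `precision_plus` is the
#' number of matched clusters over the number of clusters, `recall_plus`
#' the number of matched complexes over the number of complexes (the two
#' counts coincide, being a matching), and `f_measure_plus` their harmonic
#' mean.
#'
#' @inheritParams contingency_table
#' @param theta Affinity threshold in \[0, 1\] (inclusive).
#' @return A one-row tibble: `precision_plus`, `recall_plus`,
#'   `f_measure_plus`.
#' @export
na_prf <- function(gold, pred, theta = 0.25) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0 || theta > 1) {
    abort("`theta` must be a single number in [0, 1].")
  }
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  w <- overlap_matrix(gold, pred)
  idx <- which(w >= theta & w > 0, arr.ind = TRUE)
  n_matched <- if (nrow(idx) == 0) 0L else {
    g <- bipartite_pair_graph(length(gold), length(pred), idx)
    igraph::max_bipartite_match(g)$matching_size
  }
  p <- n_matched / length(pred)
  r <- n_matched / length(gold)
  tibble(
    precision_plus = p, recall_plus = r,
    f_measure_plus = harmonic_or_zero(p, r)
  )
}

#' Newman modularity of a node partition
#'
#' \eqn{q(C) = \sum_{C} [ E(C)/m - (\sum_{v \in C} \deg v / 2m)^2 ]},
#' where \eqn{E(C)} counts intra-cluster edges and \eqn{m} all edges:
#' the excess of intra-cluster edge mass over the expectation of a
#' degree-preserving null model.  Requires a true partition --
#' overlapping clusters are an error, as modularity is not defined for
#' them.
#'
#' @inheritParams graph_complement
#' @param clusters A complex set partitioning the nodes of `g`.
#' @return A number \eqn{\le 1}.
#' @examples
#' g <- plant_network(data.frame(kind = c("clique", "clique"), a = c(3, 3)),
#'                    noise_edges = 0, seed = 1)
#' cluster_modularity(g$graph, g$complexes)  # 0.5 for two separate triangles
#' @export
cluster_modularity <- function(g, clusters) {
  g <- as_ppi_graph(g)
  clusters <- as_complex_list(clusters)
  if (igraph::ecount(g) == 0) abort("Modularity requires a graph with >= 1 edge.")
  nodes <- unlist(clusters)
  if (any(duplicated(nodes))) abort("Modularity requires non-overlapping clusters.")
  if (!setequal(nodes, node_names(g))) {
    abort("`clusters` must partition the node set of `g`.")
  }
  memb <- integer(igraph::vcount(g))
  names(memb) <- node_names(g)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  igraph::modularity(g, memb[node_names(g)])
}

#' Composite score of the five headline measures
#'
#' The sum of MMR, FRM, SEP, ACC and the Jaccard F-measure, each in
#' \[0, 1\], giving a single score in \[0, 5\] used to rank predictors.
#'
#' @param x A `complex_metrics` object from [score_clusters()], or a named
#'   list / one-row data frame with entries `mmr`, `frm`, `sep`, `acc`,
#'   `f_measure`.
#' @return A number in \[0, 5\].
#' @export
composite_score <- function(x) {
  need <- c("mmr", "frm", "sep", "acc", "f_measure")
  if (!all(need %in% names(x))) {
    abort(sprintf("`x` must provide: %s", paste(need, collapse = ", ")))
  }
  sum(map_dbl(need, function(nm) as.numeric(x[[nm]])))
}

#' MMR + F-measure+ across affinity thresholds
#'
#' MMR does not depend on the affinity threshold; F-measure+ does, so their
#' sum traces how prediction quality decays as the match requirement
#' tightens from \eqn{\theta = 0} to 1.
#'
#' @inheritParams contingency_table
#' @param thetas Thresholds in \[0, 1\] (default a 0.05-step grid).
#' @return A tibble with columns `theta`, `mmr`, `f_measure_plus`,
#'   `mmr_f_plus`.
#' @export
mmr_fplus_curve <- function(gold, pred, thetas = seq(0, 1, by = 0.05)) {
  if (any(thetas < 0 | thetas > 1)) abort("All `thetas` must lie in [0, 1].")
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  mmr <- max_matching_ratio(gold, pred)
  fplus <- map_dbl(thetas, function(th) na_prf(gold, pred, th)$f_measure_plus)
  tibble(theta = thetas, mmr = mmr, f_measure_plus = fplus,
         mmr_f_plus = mmr + fplus)
}

#' Evaluate predicted clusters against a gold standard
#'
#' Computes the full evaluation suite for one (gold standard, prediction)
#' pair: the contingency measures SN, PPV, ACC and SEP, the match-based
#' FRM and MMR, Jaccard precision/recall/F-measure, neighborhood-affinity
#' precision+/recall+/F-measure+ at `theta`, Newman modularity of the
#' prediction on the network (when `graph` is supplied and the prediction
#' does not overlap), and the composite score MMR + FRM + SEP + ACC + F.
#'
#' @inheritParams contingency_table
#' @inheritParams na_prf
#' @param graph Optional PPI network on which `pred` was computed; enables
#'   the modularity entry.
#' @param frm_threshold Strict overlap threshold for FRM (default 0.25).
#' @param restrict_gold If `TRUE` (requires `graph`), gold complexes are
#'   first intersected with the network's node set and emptied complexes
#'   dropped, so that proteins absent from the network cannot depress
#'   recall-type measures.
#' @return A `complex_metrics` object (named list of measures) with
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' net <- plant_network(fixture_plant_specs()[[1]], noise_edges = 0, seed = 1)
#' cp <- coherent_partition(net$graph)
#' score_clusters(net$complexes, cp, graph = net$graph)
#' @export
score_clusters <- function(gold, pred, graph = NULL, theta = 0.25,
                           frm_threshold = 0.25, restrict_gold = FALSE) {
  gold <- as_complex_list(gold)
  pred <- as_complex_list(pred)
  if (restrict_gold) {
    if (is.null(graph)) abort("`restrict_gold = TRUE` requires `graph`.")
    net_nodes <- node_names(as_ppi_graph(graph))
    gold <- keep(lapply(gold, function(cx) intersect(cx, net_nodes)),
                 function(cx) length(cx) > 0)
    if (length(gold) == 0) abort("No gold complex intersects the network.")
  }
  tab <- contingency_table(gold, pred)
  spa <- sn_ppv_acc(tab)
  sep <- separation(tab)
  frm <- fraction_match(gold, pred, threshold = frm_threshold)
  mmr <- max_matching_ratio(gold, pred)
  prf <- jaccard_prf(gold, pred)
  plus <- na_prf(gold, pred, theta)
  modul <- NA_real_
  if (!is.null(graph)) {
    graph <- as_ppi_graph(graph)
    overlapping <- anyDuplicated(unlist(pred)) > 0
    covers <- setequal(unlist(pred), node_names(graph))
    if (!overlapping && covers && igraph::ecount(graph) > 0) {
      modul <- cluster_modularity(graph, pred)
    }
  }
  out <- list(
    sn = spa$sn, ppv = spa$ppv, acc = spa$acc, sep = sep,
    frm = frm, mmr = mmr,
    precision = prf$precision, recall = prf$recall, f_measure = prf$f_measure,
    precision_plus = plus$precision_plus, recall_plus = plus$recall_plus,
    f_measure_plus = plus$f_measure_plus,
    modularity = modul, theta = theta,
    n_gold = length(gold), n_pred = length(pred)
  )
  out$composite <- composite_score(out)
  structure(out, class = "complex_metrics")
}

#' @export
print.complex_metrics <- function(x, ...) {
  cat(sprintf("Complex prediction metrics (%d gold complexes, %d clusters)\n",
              x$n_gold, x$n_pred))
  df <- tidy.complex_metrics(x)
  print(as.data.frame(df), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long-format view of an evaluation report
#'
#' @param x A `complex_metrics` object.
#' @param ... Unused.
#' @return A tibble with columns `measure` and `value`.
#' @exportS3Method generics::tidy
tidy.complex_metrics <- function(x, ...) {
  nm <- c("sn", "ppv", "acc", "sep", "frm", "mmr", "precision", "recall",
          "f_measure", "precision_plus", "recall_plus", "f_measure_plus",
          "modularity", "composite")
  tibble(measure = nm, value = map_dbl(nm, function(n) as.numeric(x[[n]])))
}

#' One-row view of an evaluation report
#'
#' @inheritParams tidy.complex_metrics
#' @return A one-row tibble with one column per measure plus `theta`,
#'   `n_gold` and `n_pred`.
#' @exportS3Method generics::glance
glance.complex_metrics <- function(x, ...) {
  as_tibble(x[c("sn", "ppv", "acc", "sep", "frm", "mmr", "precision",
                "recall", "f_measure", "precision_plus", "recall_plus",
                "f_measure_plus", "modularity", "composite", "theta",
                "n_gold", "n_pred")])
}

#' Bar chart of the bounded evaluation measures
#'
#' @param object A `complex_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.complex_metrics <- function(object, ...) {
  tidy.complex_metrics(object) |>
    dplyr::filter(.data$measure != "modularity", .data$measure != "composite") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$measure, y = .data$value)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = "Cluster vs gold-standard evaluation") +
    ggplot2::theme_minimal()
}
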