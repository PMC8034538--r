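#' Build a single planted complex
#'
#' Generates one biclique-spanned component of the kind observed along the
#' density continuum of curated complexes:
#'
#' * `"star"`: one center plus `a` leaves (`a + 1` nodes, sparsest case);
#' * `"biclique"`: complete bipartite graph on parts of sizes `a` and `b`;
#' * `"clique"`: complete graph on `a` nodes (densest case);
#' * `"random_bs"`: a biclique on parts `a`, `b` plus `extra` uniformly
#'   sampled within-part edges -- an arbitrary biclique-spanned graph
#'   between those extremes (uses the current RNG state).
#'
#' Every output satisfies [is_biclique_spanned()] by construction.
#'
#' @param kind One of `"star"`, `"biclique"`, `"clique"`, `"random_bs"`.
#' @param a,b Size parameters (see above); `b` only for the bipartite
#'   kinds.  Stars need at least 1 leaf, cliques at least 2 nodes,
#'   biclique parts at least 1 node each.
#' @param extra Number of additional within-part edges for `"random_bs"`.
#' @param id_prefix Node identifiers are `"<id_prefix>_n<j>"`.
#' @return An `igraph` component.
#' @examples
#' igraph::ecount(make_complex("biclique", 2, 3))  # 6
#' @export
make_complex <- function(kind = c("star", "biclique", "clique", "random_bs"),
                         a, b = NULL, extra = 0, id_prefix = "c1") {
  kind <- match.arg(kind)
  a <- as.integer(a)
  ids <- function(n) paste0(id_prefix, "_n", seq_len(n))
  edges <- switch(kind,
    star = {
      if (a < 1) abort("A star needs at least 1 leaf.")
      v <- ids(a + 1)
      cbind(v[1], v[-1])
    },
    clique = {
      if (a < 2) abort("A clique needs at least 2 nodes.")
      t(combn(ids(a), 2))
    },
    biclique = ,
    random_bs = {
      b <- as.integer(b %||% abort("`b` (second part size) is required."))
      if (is.na(a) || is.na(b) || a < 1 || b < 1) {
        abort("Biclique parts must have at least 1 node each.")
      }
      v <- ids(a + b)
      left <- v[seq_len(a)]
      right <- v[a + seq_len(b)]
      base <- cbind(rep(left, each = b), rep(right, times = a))
      if (kind == "random_bs" && extra > 0) {
        within <- rbind(
          if (a >= 2) t(combn(left, 2)),
          if (b >= 2) t(combn(right, 2))
        )
        if (is.null(within) || nrow(within) < extra) {
          abort("`extra` exceeds the number of available within-part pairs.")
        }
        base <- rbind(base, within[sample.int(nrow(within), extra), , drop = FALSE])
      }
      base
    }
  )
  ppi_graph(edges)
}

#' Generate a network with planted complexes and noise edges
#'
#' Simulates the generative picture behind the partitioner: a set of
#' ground-truth protein complexes, each a biclique-spanned component, plus
#' spurious inter-complex interactions.  The components specified by
#' `spec` are laid down disjointly with globally unique node identifiers
#' (`"c<i>_n<j>"` for complex `i`), then exactly `noise_edges` edges are
#' sampled uniformly without replacement from the node pairs lying in
#' *different* complexes.  Noise never lands inside a complex, so the
#' planted truth stays biclique spanned regardless of the noise level.
#' The same `seed` always reproduces the identical network.
#'
#' @param spec A data frame with columns `kind` (see [make_complex()]),
#'   `a`, and optionally `b` and `extra`.
#' @param noise_edges Number of inter-complex edges to add (error if it
#'   exceeds the number of available pairs).
#' @param seed Integer seed driving all randomness.
#' @return An object of class `planted_network`: list with `graph` (the
#'   network), `complexes` (the ground truth, a complex-set list), `spec`,
#'   `noise` (tibble of the added edges) and `seed`.
#' @examples
#' net <- plant_network(data.frame(kind = c("star", "clique"), a = c(4, 4)),
#'                      noise_edges = 2, seed = 7)
#' igraph::ecount(net$graph)  # 4 + 6 + 2
#' @export
plant_network <- function(spec, noise_edges = 0, seed = 1L) {
  if (!is.data.frame(spec) || nrow(spec) == 0 || !all(c("kind", "a") %in% names(spec))) {
    abort("`spec` must be a data frame with columns `kind` and `a`.")
  }
  noise_edges <- as.integer(noise_edges)
  if (noise_edges < 0) abort("`noise_edges` must be non-negative.")
  withr::local_seed(as.integer(seed))
  comps <- lapply(seq_len(nrow(spec)), function(i) {
    make_complex(
      kind = spec$kind[i], a = spec$a[i],
      b = if ("b" %in% names(spec)) spec$b[i] else NULL,
      extra = if ("extra" %in% names(spec)) spec$extra[i] %||% 0 else 0,
      id_prefix = paste0("c", i)
    )
  })
  complexes <- lapply(comps, node_names)
  edge_mats <- lapply(comps, function(g) igraph::as_edgelist(g))
  edges <- do.call(rbind, edge_mats)

  noise <- tibble(from = character(0), to = character(0))
  if (noise_edges > 0) {
    sizes <- lengths(complexes)
    n_pairs <- (sum(sizes)^2 - sum(sizes^2)) / 2
    if (noise_edges > n_pairs) {
      abort(sprintf(
        "`noise_edges` (%d) exceeds the %d available inter-complex pairs.",
        noise_edges, n_pairs
      ))
    }
    pairs <- do.call(rbind, unlist(lapply(seq_along(complexes), function(i) {
      lapply(seq_along(complexes)[-seq_len(i)], function(j) {
        cbind(rep(complexes[[i]], each = sizes[j]),
              rep(complexes[[j]], times = sizes[i]))
      })
    }), recursive = FALSE))
    pick <- pairs[sample.int(nrow(pairs), noise_edges), , drop = FALSE]
    noise <- tibble(from = pmin(pick[, 1], pick[, 2]),
                    to = pmax(pick[, 1], pick[, 2])) |>
      arrange(.data$from, .data$to)
    edges <- rbind(edges, pick)
  }
  structure(
    list(
      graph = ppi_graph(edges),
      complexes = complexes,
      spec = as_tibble(spec),
      noise = noise,
      seed = as.integer(seed)
    ),
    class = "planted_network"
  )
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf(
    "Planted network: %d complexes, %d nodes, %d edges (%d noise), seed %d\n",
    length(x$complexes), igraph::vcount(x$graph), igraph::ecount(x$graph),
    nrow(x$noise), x$seed
  ))
  invisible(x)
}

#' Canonical planted-complex validation specs
#'
#' A fixed suite of plant specifications mixing the three archetypes
#' (stars with 2--8 leaves, bicliques with parts up to (4, 5), cliques up
#' to 7 nodes, and random biclique-spanned fillers) used throughout the
#' package's validation: at zero noise the partitioner must recover each
#' suite member exactly.
#'
#' @return A named list of spec tibbles suitable for [plant_network()].
#' @export
fixture_plant_specs <- function() {
  list(
    stars = tibble(
      kind = "star", a = c(2L, 4L, 8L), b = NA_integer_, extra = 0L
    ),
    bicliques = tibble(
      kind = "biclique", a = c(1L, 2L, 4L), b = c(3L, 3L, 5L), extra = 0L
    ),
    cliques = tibble(
      kind = "clique", a = c(2L, 3L, 5L, 7L), b = NA_integer_, extra = 0L
    ),
    mixed_small = tibble(
      kind = c("star", "biclique", "clique"),
      a = c(3L, 2L, 4L), b = c(NA, 4L, NA), extra = 0L
    ),
    mixed_large = tibble(
      kind = c("star", "star", "biclique", "clique", "random_bs"),
      a = c(2L, 6L, 3L, 6L, 3L), b = c(NA, NA, 4L, NA, 3L),
      extra = c(0L, 0L, 0L, 0L, 2L)
    )
  )
}
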