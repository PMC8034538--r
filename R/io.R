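#' Read a PPI network from a tab/whitespace-separated edge list
#'
#' Parses the flat pair-list format common to PPI exports (STRING-style
#' after preprocessing): one interaction per line, two whitespace- or
#' tab-separated protein identifiers, an optional third confidence column
#' (ignored, with a message), `#`-prefixed comment lines and blank lines
#' skipped.  Duplicate edges and self-loops are dropped with a message.
#'
#' @param path Path to the edge-list file.
#' @return A simple undirected named `igraph` (see [ppi_graph()]); an
#'   empty file yields the empty graph.
#' @export
read_ppi_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(ppi_graph(data.frame(from = character(0), to = character(0))))
  }
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- lengths(toks) < 2
  if (any(bad)) {
    abort(sprintf(
      "Malformed edge-list line %d: expected at least 2 columns, found %d.",
      idx[which(bad)[1]], lengths(toks)[which(bad)[1]]
    ))
  }
  if (any(lengths(toks) > 2)) {
    inform(sprintf(
      "Ignoring extra column(s) (e.g. confidence weights) on %d line(s).",
      sum(lengths(toks) > 2)
    ))
  }
  ppi_graph(data.frame(
    from = map_chr(toks, 1), to = map_chr(toks, 2),
    stringsAsFactors = FALSE
  ))
}

#' Read a flat complex catalogue
#'
#' One complex per line, whitespace-separated member identifiers (the
#' CYC2008/SGD/CORUM flat-file style).  Duplicate members within a line
#' are removed; blank lines are skipped.  An empty catalogue is an error,
#' since evaluation against an empty gold standard is meaningless.
#'
#' @param path Path to the complex file.
#' @return A complex-set list (see [as_complex_list()]).
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort("Complex catalogue is empty.")
  as_complex_list(strsplit(trimws(lines), "\\s+"))
}

#' Write clusters (or complexes) to a flat file
#'
#' Inverse of [read_complexes()]: one cluster per line, members sorted
#' lexicographically, clusters ordered by decreasing size then first
#' member.  Round-trips through [read_complexes()] up to that ordering
#' normalization.
#'
#' @param x A `coherent_partition` or a complex-set list.
#' @param path Output path.
#' @param min_size Drop clusters with fewer members before writing
#'   (default 1 = keep all; the partitioning itself never filters).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path, min_size = 1) {
  is_partition <- inherits(x, "coherent_partition")
  empty <- (is_partition && length(x$clusters) == 0) ||
    (is.list(x) && !is_partition && length(x) == 0)
  clusters <- if (empty) list() else as_complex_list(x)
  clusters <- clusters[lengths(clusters) >= min_size]
  clusters <- clusters[order(
    -lengths(clusters), map_chr(clusters, function(cl) cl[1] %||% ""),
    method = "radix"
  )]
  writeLines(map_chr(clusters, paste, collapse = "\t"), path)
  if (is_partition) {
    inform(sprintf("Wrote %d cluster(s); edge cut of %d edge(s).",
                   length(clusters), nrow(x$edge_cut)))
  } else {
    inform(sprintf("Wrote %d cluster(s).", length(clusters)))
  }
  invisible(path)
}

#' Write an evaluation report to TSV or JSON
#'
#' @param x A `complex_metrics` object from [score_clusters()].
#' @param path Output path.
#' @param format `"tsv"` (one measure per row) or `"json"` (one object).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "complex_metrics"))
  if (format == "tsv") {
    df <- tidy.complex_metrics(x)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    vals <- as.list(glance.complex_metrics(x))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Write a planted network to fixture files
#'
#' Emits the edge list (TSV) and the ground-truth complexes (flat file) of
#' a [plant_network()] result, for use as an on-disk test fixture.
#'
#' @param x A `planted_network`.
#' @param network_path,complexes_path Output paths.
#' @return A named character vector of the two paths, invisibly.
#' @export
write_planted <- function(x, network_path, complexes_path) {
  stopifnot(inherits(x, "planted_network"))
  en <- igraph::as_edgelist(x$graph)
  en <- cbind(pmin(en[, 1], en[, 2]), pmax(en[, 1], en[, 2]))
  en <- en[order(en[, 1], en[, 2], method = "radix"), , drop = FALSE]
  writeLines(paste(en[, 1], en[, 2], sep = "\t"), network_path)
  write_clusters(x$complexes, complexes_path)
  invisible(c(network = network_path, complexes = complexes_path))
}
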