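#' Read an undirected interactome from a two-column edge list
#'
#' Parses a delimited text file of interacting gene pairs into a simple
#' undirected \pkg{igraph} graph.  Lines starting with \code{#} and blank
#' lines are ignored; node names are whitespace-trimmed with case
#' preserved.  Self-loops and duplicate edges are dropped (a message
#' reports how many), so the result is always a simple graph.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab.
#' @param header logical; if \code{TRUE} the first non-comment line is
#'   skipped.
#' @return an undirected simple \code{igraph} graph with vertex names.
#' @export
read_edge_list <- function(path, delimiter = "\t", header = FALSE) {
  if (!file.exists(path)) stop(sprintf("edge list file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (header && length(idx) > 0L) idx <- idx[-1L]
  if (length(idx) == 0L) stop(sprintf("edge list file is empty: %s", path))
  parts <- strsplit(lines[idx], delimiter, fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d in %s: fewer than 2 columns",
                 idx[bad[1L]], path))
  }
  a <- trimws(vapply(parts, `[[`, "", 1L))
  b <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    j <- which(!nzchar(a) | !nzchar(b))[1L]
    stop(sprintf("malformed edge list line %d in %s: empty gene symbol",
                 idx[j], path))
  }
  edges_from_pairs(a, b)
}

#' Build a simple undirected graph from paired gene vectors
#'
#' @param a,b character vectors of equal length giving edge endpoints.
#' @return an undirected simple \code{igraph} graph.
#' @export
edges_from_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  self <- a == b
  n_self <- sum(self)
  a2 <- a[!self]
  b2 <- b[!self]
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_self > 0L) message(sprintf("dropped %d self-loop(s)", n_self))
  if (n_dup > 0L) message(sprintf("dropped %d duplicate edge(s)", n_dup))
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Write a graph as a two-column tab-separated edge list
#'
#' Edges are written with endpoints in lexicographic order, sorted, so a
#' load/write/load cycle reproduces an identical edge set.
#'
#' @param g an igraph graph with vertex names.
#' @param path output file path.
#' @export
write_edge_list <- function(g, path) {
  .assert_graph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  o <- order(lo, hi)
  writeLines(paste(lo[o], hi[o], sep = "\t"), path)
  invisible(path)
}

#' Largest connected component of a graph
#'
#' Returns the induced subgraph on the largest connected vertex set.  If
#' several components tie for the maximum size, the component containing
#' the lexicographically smallest vertex name is chosen, making the result
#' deterministic.
#'
#' @param g an igraph graph with vertex names.
#' @return the induced subgraph on the winning component.
#' @export
largest_component <- function(g) {
  .assert_graph(g)
  if (igraph::vcount(g) == 0L) stop("cannot take the largest component of an empty graph")
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1L) {
    # tie-break: component whose smallest member sorts first
    firsts <- vapply(cand, function(ci) {
      min(.node_names(g)[comp$membership == ci])
    }, "")
    cand <- cand[order(firsts)][1L]
  }
  keep <- .node_names(g)[comp$membership == cand[1L]]
  induced_network(g, keep)
}

#' Induced subgraph on a gene set
#'
#' Genes absent from the graph are ignored (a message reports how many).
#'
#' @param g an igraph graph with vertex names.
#' @param genes character vector of gene symbols.
#' @return induced subgraph on \code{intersect(genes, V(g))}.
#' @export
induced_network <- function(g, genes) {
  .assert_graph(g)
  genes <- unique(genes)
  absent <- setdiff(genes, .node_names(g))
  if (length(absent) > 0L) {
    message(sprintf("%d gene(s) not in graph, ignored", length(absent)))
  }
  igraph::induced_subgraph(g, intersect(genes, .node_names(g)))
}

#' Partition a gene set by graph membership
#'
#' @param g an igraph graph with vertex names.
#' @param genes character vector of gene symbols.
#' @return list with components \code{mapped} and \code{unmapped} (both
#'   sorted character vectors).
#' @export
map_gene_set <- function(g, genes) {
  .assert_graph(g)
  genes <- unique(genes)
  mapped <- sort(intersect(genes, .node_names(g)))
  unmapped <- sort(setdiff(genes, .node_names(g)))
  message(sprintf("mapped %d/%d gene(s) to the graph", length(mapped), length(genes)))
  list(mapped = mapped, unmapped = unmapped)
}

#' Read a newline-delimited gene set
#'
#' @param path text file, one gene symbol per line; \code{#} comments and
#'   blank lines ignored.
#' @return character vector of gene symbols.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' @rdname read_gene_set
#' @param genes character vector to write.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors (names = set names).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) {
    if (length(p) < 2L) stop("malformed GMT line: fewer than 2 fields")
    unique(p[-c(1L, 2L)])
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
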