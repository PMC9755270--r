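#' Simple random-walk transition matrix
#'
#' Row-stochastic matrix of the unbiased random walk:
#' \eqn{P_{ij} = 1/\deg(v_i)} when \eqn{(v_i, v_j)} is an edge, else 0.
#'
#' @param g connected igraph graph with vertex names and no isolated
#'   vertices.
#' @return dense numeric matrix with vertex names as dimnames.
#' @export
transition_matrix <- function(g) {
  .assert_graph(g)
  deg <- igraph::degree(g)
  if (any(deg == 0L)) stop("graph has isolated vertices; transition matrix undefined")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  P <- A / deg  # divides each row i by deg[i] (column-recycling over rows)
  dimnames(P) <- list(.node_names(g), .node_names(g))
  P
}

#' Expected-visits matrix of a k-step random walk
#'
#' \code{he[i, j]} is the expected number of time points \eqn{t = 0,
#' \dots, k} at which a k-step simple random walk started at \eqn{v_i}
#' occupies \eqn{v_j}; in matrix form \eqn{\sum_{t=0}^{k} P^t}.  The
#' \eqn{t = 0} term (the walker occupies its start before moving) is
#' included, which gives every row the sum \eqn{k + 1}.
#'
#' @param g connected igraph graph with vertex names.
#' @param k walk length, at least 1.
#' @return object of class \code{dsd_state}: list with \code{node_order},
#'   \code{k} and the dense matrix \code{he}.
#' @export
he_matrix <- function(g, k = 5L) {
  if (k < 1L) stop("walk length k must be >= 1")
  P <- transition_matrix(g)
  H <- diag(nrow(P))
  Pt <- diag(nrow(P))
  for (t in seq_len(k)) {
    Pt <- Pt %*% P
    H <- H + Pt
  }
  dimnames(H) <- dimnames(P)
  structure(list(node_order = rownames(P), k = as.integer(k), he = H),
            class = "dsd_state")
}

#' Pairwise diffusion state distances
#'
#' \eqn{DSD(v_i, v_j) = \lVert He(v_i) - He(v_j) \rVert_1}: the L1
#' distance between the expected-visit vectors of the two start vertices.
#' For any fixed walk length k this is a metric on the vertex set.
#'
#' @param state \code{dsd_state} from \code{\link{he_matrix}}.
#' @return object of class \code{dsd_matrix}: list with \code{node_order},
#'   \code{k} and the dense symmetric distance matrix \code{d}.
#' @export
dsd_matrix <- function(state) {
  stopifnot(inherits(state, "dsd_state"))
  d <- as.matrix(dist(state$he, method = "manhattan"))
  dimnames(d) <- list(state$node_order, state$node_order)
  structure(list(node_order = state$node_order, k = state$k, d = d),
            class = "dsd_matrix")
}

#' Average DSD from a vertex to a target set
#'
#' Arithmetic mean of \code{DSD(node, t)} over the targets; if the vertex
#' itself belongs to the target set its zero self-distance is included,
#' mirroring the treatment of self shortest-path distances in proximity.
#'
#' @param dm \code{dsd_matrix}.
#' @param node vertex name.
#' @param targets nonempty character vector of vertex names.
#' @return numeric scalar.
#' @export
average_dsd <- function(dm, node, targets) {
  stopifnot(inherits(dm, "dsd_matrix"))
  if (length(targets) == 0L) stop("targets must be nonempty")
  bad <- setdiff(c(node, targets), dm$node_order)
  if (length(bad) > 0L) {
    stop(sprintf("vertex not in DSD matrix: %s", paste(head(bad, 3L), collapse = ", ")))
  }
  mean(dm$d[node, targets])
}

#' Write / read a DSD matrix as TSV with a node header row and column
#'
#' @param dm \code{dsd_matrix}.
#' @param path file path.
#' @export
write_dsd_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dsd_matrix"))
  df <- data.frame(node = dm$node_order, dm$d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dsd_matrix
#' @param k walk length to record on the restored object (not stored in
#'   the TSV).
#' @export
read_dsd_matrix <- function(path, k = NA_integer_) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nodes <- df[[1L]]
  d <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(d) <- list(nodes, colnames(df)[-1L])
  d <- d[, nodes, drop = FALSE]
  structure(list(node_order = nodes, k = as.integer(k), d = d),
            class = "dsd_matrix")
}
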