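#' Local radiality of a vertex with respect to a module
#'
#' \eqn{LR_i = \sum_{g \in RM} spl(i, g) / |RM|}: the mean shortest-path
#' length from the vertex to the module (lower is better).  Identical in
#' form to \code{\link{avg_shortest_path_to_set}}; kept as the named
#' reference prioritizer applied to the Response module.
#'
#' @param g connected igraph graph with vertex names.
#' @param node vertex name.
#' @param response nonempty character vector of Response-module vertex
#'   names.
#' @return numeric scalar.
#' @export
local_radiality <- function(g, node, response) {
  avg_shortest_path_to_set(g, node, response)
}

#' @rdname local_radiality
#' @return \code{local_radiality_scores}: object of class
#'   \code{baseline_scores} covering every vertex (orientation
#'   lower-is-better).
#' @export
local_radiality_scores <- function(g, response) {
  .assert_graph(g)
  if (length(response) == 0L) stop("response set must be nonempty")
  .assert_in_graph(g, response, "response")
  D <- igraph::distances(g, to = unique(response))
  scores <- rowMeans(D)
  names(scores) <- .node_names(g)
  structure(list(method = "local_radiality", scores = scores,
                 orientation = "lower"), class = "baseline_scores")
}

#' Random walk with restart (personalized PageRank) scores
#'
#' Power iteration of \eqn{p \leftarrow \alpha P^{\top} p + (1 - \alpha)
#' v}, where P is the row-stochastic transition matrix, v puts mass
#' \eqn{1/|S|} on each seed, and \eqn{\alpha} is the damping (walk
#' continuation) probability.  Iterates until the L1 change drops below
#' \code{tol}.  Scores sum to 1; higher is better.
#'
#' @param g connected igraph graph with vertex names.
#' @param seeds nonempty character vector of seed vertex names.
#' @param damping continuation probability in (0, 1), default 0.85.
#' @param tol L1 convergence tolerance, default 1e-8.
#' @param max_iter iteration cap.
#' @return object of class \code{baseline_scores} (orientation
#'   higher-is-better).
#' @export
rwr_scores <- function(g, seeds, damping = 0.85, tol = 1e-8,
                       max_iter = 10000L) {
  .assert_graph(g)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("seed set must be nonempty")
  .assert_in_graph(g, seeds, "seeds")
  if (damping <= 0 || damping >= 1) stop("damping must be in (0, 1)")
  nm <- .node_names(g)
  n <- length(nm)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- igraph::degree(g)
  if (any(deg == 0L)) stop("graph has isolated vertices")
  # column-stochastic walk operator: W = t(P) with P = D^-1 A
  W <- Matrix::t(A / deg)
  v <- setNames(rep(0, n), nm)
  v[seeds] <- 1 / length(seeds)
  p <- v
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric(damping * (W %*% p)) + (1 - damping) * v
    delta <- sum(abs(p_new - p))
    p <- setNames(p_new, nm)
    if (delta < tol) {
      return(structure(list(method = "rwr", scores = p,
                            orientation = "higher", iterations = it),
                       class = "baseline_scores"))
    }
  }
  stop(sprintf("random walk with restart did not converge in %d iterations", max_iter))
}

#' Cosine similarity of a vertex embedding to a seed set
#'
#' \eqn{n2v_i = \max_j x_i \cdot x_j / (\lVert x_i \rVert_2 \lVert x_j
#' \rVert_2)} over seeds j; vertices belonging to the seed set score
#' exactly 1.  Higher is better.
#'
#' @param emb numeric matrix of embeddings, rownames = vertex names, no
#'   zero-norm rows.
#' @param node vertex name.
#' @param seeds nonempty character vector of seed vertex names.
#' @return numeric scalar.
#' @export
node2vec_similarity <- function(emb, node, seeds) {
  seeds <- unique(as.character(seeds))
  missing <- setdiff(c(node, seeds), rownames(emb))
  if (length(missing) > 0L) {
    stop(sprintf("no embedding for vertex: %s", paste(head(missing, 3L), collapse = ", ")))
  }
  if (node %in% seeds) return(1)
  x <- emb[node, ]
  nx <- sqrt(sum(x^2))
  sims <- vapply(seeds, function(s) {
    y <- emb[s, ]
    sum(x * y) / (nx * sqrt(sum(y^2)))
  }, 0)
  max(sims)
}

#' @rdname node2vec_similarity
#' @return \code{embedding_scores}: object of class
#'   \code{baseline_scores} covering every embedded vertex.
#' @export
embedding_scores <- function(emb, seeds) {
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, rownames(emb))
  if (length(missing) > 0L) {
    stop(sprintf("no embedding for vertex: %s", paste(head(missing, 3L), collapse = ", ")))
  }
  norms <- sqrt(rowSums(emb^2))
  if (any(norms == 0)) stop("embedding has zero-norm vectors")
  X <- emb / norms
  sims <- X %*% t(X[seeds, , drop = FALSE])
  scores <- apply(sims, 1L, max)
  scores[seeds] <- 1
  names(scores) <- rownames(emb)
  structure(list(method = "node2vec", scores = scores,
                 orientation = "higher"), class = "baseline_scores")
}

#' Deterministic spectral embedding of a graph
#'
#' Leading eigenvectors of the adjacency matrix, each scaled by
#' \eqn{\sqrt{|\lambda|}} and sign-fixed (largest-magnitude entry
#' positive), with a constant anchor column appended so no vertex has a
#' zero-norm vector.  Used as the in-package deterministic producer of
#' embedding tables for cosine-similarity scoring; externally trained
#' embeddings (e.g. node2vec, conventionally 128-dimensional) can be
#' supplied through \code{\link{read_embeddings}} instead.
#'
#' @param g connected igraph graph with vertex names.
#' @param dim embedding dimension (>= 2).
#' @return numeric matrix, one row per vertex.
#' @export
spectral_embedding <- function(g, dim = 16L) {
  .assert_graph(g)
  n <- igraph::vcount(g)
  if (dim < 2L) stop("dim must be >= 2")
  if (dim > n) stop("dim cannot exceed the number of vertices")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  eg <- eigen(A, symmetric = TRUE)
  k <- dim - 1L
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
    vec[, j] <- vec[, j] * sqrt(abs(eg$values[j]))
  }
  out <- cbind(vec, anchor = 0.1)
  rownames(out) <- .node_names(g)
  colnames(out) <- c(paste0("v", seq_len(k)), "anchor")
  out
}

#' Read / write an embedding table as TSV (node, v1..vd)
#'
#' @param path file path.
#' @return numeric matrix with vertex names as rownames.
#' @export
read_embeddings <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("embedding table contains non-finite entries")
  if (any(sqrt(rowSums(m^2)) == 0)) stop("embedding table contains zero-norm vectors")
  m
}

#' @rdname read_embeddings
#' @param emb numeric matrix to write.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(node = rownames(emb), emb, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
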