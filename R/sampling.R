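# log2 degree bin index: bin k holds degrees in [2^k, 2^(k+1)); degree 0
# gets its own bin -1
.degree_bin <- function(deg) {
  b <- ifelse(deg == 0L, -1L, as.integer(floor(log2(pmax(deg, 1L)))))
  as.integer(b)
}

#' Sample a degree-matched random gene set
#'
#' Draws \code{length(template)} distinct vertices, each taken uniformly
#' without replacement from the logarithmic degree bin (bin \eqn{k} holds
#' degrees in \eqn{[2^k, 2^{k+1})}) of the corresponding template vertex.
#' A bin holding fewer than twice the requested number of vertices is
#' merged upward into the next occupied bin (reported via a message);
#' exact-degree matching is infeasible for high-degree hubs, which is why
#' degree-preserving null models conventionally bin degrees
#' logarithmically.
#'
#' @param g connected igraph graph with vertex names.
#' @param template character vector of vertex names to match (subset of
#'   \code{V(g)}).
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return character vector of sampled vertex names, same length as
#'   \code{template}.
#' @export
sample_degree_matched_set <- function(g, template, seed = NULL) {
  .assert_graph(g)
  template <- unique(as.character(template))
  if (length(template) == 0L) return(character(0L))
  .assert_in_graph(g, template, "template")
  deg <- igraph::degree(g)
  node_bin <- .degree_bin(deg)
  need_tab <- table(.degree_bin(deg[template]))
  bins <- sort(unique(node_bin))
  need <- setNames(rep(0L, length(bins)), bins)
  need[names(need_tab)] <- as.integer(need_tab)

  .with_seed(seed, {
    out <- character(0L)
    pool <- character(0L)
    pending <- 0L
    for (i in seq_along(bins)) {
      b <- bins[i]
      pool <- c(pool, names(deg)[node_bin == b])
      pending <- pending + need[[as.character(b)]]
      if (pending == 0L) {
        pool <- character(0L)
        next
      }
      if (length(pool) >= 2L * pending || i == length(bins)) {
        if (i == length(bins) && length(pool) < 2L * pending) {
          if (length(pool) < pending) {
            stop(sprintf(
              "cannot draw %d degree-matched vertices: only %d available after bin merging",
              pending, length(pool)))
          }
          message("merged top degree bins to satisfy the requested sample")
        }
        out <- c(out, sample(pool, pending, replace = FALSE))
        pool <- character(0L)
        pending <- 0L
      } else {
        message(sprintf("degree bin %d merged upward (%d available < 2 x %d requested)",
                        b, length(pool), pending))
      }
    }
    out
  })
}

#' Sample a connected induced subgraph approximately uniformly
#'
#' Draws a vertex set of exactly \code{size} whose induced subgraph is
#' connected, approximately uniformly over all such sets.  Each draw runs
#' an independent Metropolis swap chain (swap one boundary vertex in, one
#' member out, accept connected states with a boundary-size correction so
#' the uniform distribution is stationary) for \code{iterations} burn-in
#' steps from a randomly grown connected seed set.
#'
#' The default burn-in of \code{20 * vcount(g)} steps keeps the empirical
#' distribution within total-variation distance 0.05 of uniform on small
#' graphs where exhaustive enumeration is possible (see
#' \code{\link{enumerate_connected_subgraphs}}).
#'
#' @param g connected igraph graph with vertex names.
#' @param size number of vertices to draw, between 1 and \code{vcount(g)}.
#' @param seed integer seed, or \code{NULL} for the current RNG state.
#' @param n_draws number of independent sets to draw.
#' @param iterations Metropolis burn-in steps per draw.
#' @return for \code{n_draws = 1} a character vector of vertex names;
#'   otherwise a list of such vectors.
#' @export
sample_connected_subgraph <- function(g, size, seed = NULL, n_draws = 1L,
                                      iterations = NULL) {
  .assert_graph(g)
  n <- igraph::vcount(g)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  if (size < 1L || size > n) {
    stop(sprintf("size must be between 1 and %d (got %s)", n, size))
  }
  iterations <- as.integer(iterations %||% max(100L, 20L * n))
  nm <- .node_names(g)
  sets <- .with_seed(seed, {
    if (size == n) {
      replicate(n_draws, nm, simplify = FALSE)
    } else {
      m <- nrs_sample_cpp(.adj_list0(g), as.integer(size), as.integer(n_draws),
                          iterations)
      lapply(seq_len(nrow(m)), function(i) sort(nm[m[i, ]]))
    }
  })
  if (n_draws == 1L) sets[[1L]] else sets
}

#' Enumerate every connected induced subgraph of a given size
#'
#' Brute-force enumeration used as the exact oracle for the connected
#' subgraph sampler; guarded to graphs of at most 12 vertices.
#'
#' @param g igraph graph with vertex names, at most 12 vertices.
#' @param size subgraph size.
#' @return list of sorted character vectors, each a connected vertex set,
#'   in canonical (lexicographic) order with no duplicates.
#' @export
enumerate_connected_subgraphs <- function(g, size) {
  .assert_graph(g)
  n <- igraph::vcount(g)
  if (n > 12L) {
    stop("graph too large for exhaustive enumeration; use sample_connected_subgraph()")
  }
  if (size < 1L || size > n) return(list())
  nm <- .node_names(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  combos <- utils::combn(n, size, simplify = FALSE)
  is_conn <- function(idx) {
    if (length(idx) == 1L) return(TRUE)
    sub <- A[idx, idx, drop = FALSE]
    seen <- c(TRUE, rep(FALSE, length(idx) - 1L))
    stack <- 1L
    while (length(stack) > 0L) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      nb <- which(sub[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    all(seen)
  }
  out <- lapply(combos[vapply(combos, is_conn, TRUE)],
                function(idx) sort(nm[idx]))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}
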