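#' Average shortest-path distance from a vertex to a set
#'
#' Mean unweighted shortest-path length from \code{node} to each member of
#' \code{s}; the zero self-distance is included when \code{node} belongs
#' to \code{s}.
#'
#' @param g connected igraph graph with vertex names.
#' @param node vertex name.
#' @param s nonempty character vector of vertex names.
#' @return numeric scalar.
#' @export
avg_shortest_path_to_set <- function(g, node, s) {
  .assert_graph(g)
  if (length(s) == 0L) stop("target set must be nonempty")
  .assert_in_graph(g, c(node, s))
  d <- igraph::distances(g, v = node, to = unique(s))
  if (any(!is.finite(d))) stop("unreachable target: graph is not connected")
  mean(d)
}

#' Null distribution of a per-node statistic over random connected modules
#'
#' Draws \code{n_modules} connected subgraphs of \code{module_size}
#' approximately uniformly (\code{\link{sample_connected_subgraph}}) and
#' evaluates, for the given vertex, either the average shortest-path
#' distance or the average DSD to each random module.  The empirical mean
#' and standard deviation parameterize the proximity / selectivity
#' Z-scores.
#'
#' @param g connected igraph graph.
#' @param statistic \code{"avg_shortest_path"} or \code{"avg_dsd"}.
#' @param node vertex name.
#' @param module_size size of each random module.
#' @param n_modules number of random modules (default 500).
#' @param seed integer seed, or \code{NULL}.
#' @param dm \code{dsd_matrix}, required for \code{statistic = "avg_dsd"}.
#' @return object of class \code{null_distribution}: list with
#'   \code{samples}, \code{mu}, \code{sigma}, \code{module_size},
#'   \code{n_modules}, \code{statistic}.
#' @export
null_distribution <- function(g, statistic = c("avg_shortest_path", "avg_dsd"),
                              node, module_size, n_modules = 500L,
                              seed = NULL, dm = NULL) {
  statistic <- match.arg(statistic)
  .assert_graph(g)
  if (module_size < 1L) stop("module_size must be >= 1")
  modules <- sample_connected_subgraph(g, module_size, seed = seed,
                                       n_draws = n_modules)
  if (n_modules == 1L) modules <- list(modules)
  samples <- if (statistic == "avg_shortest_path") {
    d <- igraph::distances(g, v = node)[1L, ]
    vapply(modules, function(m) mean(d[m]), 0)
  } else {
    if (is.null(dm)) stop("dm (dsd_matrix) is required for the avg_dsd statistic")
    drow <- dm$d[node, ]
    vapply(modules, function(m) mean(drow[m]), 0)
  }
  mu <- mean(samples)
  sigma <- sd(samples)
  if (n_modules == 1L) {
    sigma <- 0
    warning("n_modules = 1 gives an undefined spread; sigma set to 0 sentinel")
  }
  structure(list(samples = samples, mu = mu, sigma = sigma,
                 module_size = as.integer(module_size),
                 n_modules = as.integer(n_modules), statistic = statistic),
            class = "null_distribution")
}

.z_score <- function(observed, null) {
  if (null$sigma == 0) {
    if (observed == null$mu) return(0)
    warning("null sigma = 0; z set to signed-infinity sentinel")
    return(sign(observed - null$mu) * Inf)
  }
  (observed - null$mu) / null$sigma
}

#' Proximity Z-score
#'
#' \eqn{proximity = (\bar{d} - \mu_p) / \sigma_p}: how much closer (more
#' negative) or farther the vertex is from the Genotype module than from
#' random connected modules of the same size.
#'
#' @param d_bar observed average shortest-path distance to the module.
#' @param null \code{null_distribution} of the same statistic.
#' @return numeric Z-score; negative means closer than random.
#' @export
proximity_score <- function(d_bar, null) .z_score(d_bar, null)

#' Selectivity Z-score
#'
#' \eqn{selectivity = (\overline{DSD} - \mu_s) / \sigma_s}: how much more
#' diffusion-similar the vertex is to the Treatment module than to random
#' connected modules of the same size.  Negative means more functionally
#' similar than random.
#'
#' @param dsd_bar observed average DSD to the module.
#' @param null \code{null_distribution} of the avg_dsd statistic.
#' @return numeric Z-score.
#' @export
selectivity_score <- function(dsd_bar, null) .z_score(dsd_bar, null)

#' Rank values with average ties
#'
#' Rank 1 is best.  With \code{ascending = TRUE} (the convention for both
#' proximity and selectivity, where more negative is better) smaller
#' values rank first; tied values share the mean of their positions.
#'
#' @param values numeric vector without NAs.
#' @param ascending logical.
#' @return numeric vector of ranks in [1, n].
#' @export
rank_with_ties <- function(values, ascending = TRUE) {
  if (any(is.na(values))) stop("NA values cannot be ranked")
  if (ascending) rank(values, ties.method = "average")
  else rank(-values, ties.method = "average")
}

#' Rank product of the proximity and selectivity ranks
#'
#' \eqn{r = \sqrt{r_p \cdot r_s}}, the geometric mean of the two ranks.
#'
#' @param r_p,r_s numeric ranks, both at least 1.
#' @return numeric combined rank.
#' @export
combined_rank <- function(r_p, r_s) {
  if (any(r_p <= 0) || any(r_s <= 0)) stop("ranks must be positive")
  sqrt(r_p * r_s)
}

#' Score and rank every vertex by proximity and selectivity
#'
#' For each vertex of the graph computes the average shortest-path
#' distance to the Genotype module and the average DSD to the Treatment
#' module, converts both to Z-scores against null distributions built
#' from shared pools of random connected modules (one pool per module
#' size, \code{n_modules} draws each, reused across vertices; the pooled
#' statistics are exchangeable across vertices so sharing the pool leaves
#' the per-vertex null distribution unchanged), ranks both Z-scores
#' ascending, and combines the ranks by rank product.
#'
#' @param g connected igraph graph with vertex names.
#' @param genotype \code{network_module} (or character vector) whose LCC
#'   members define the Genotype module.
#' @param treatment \code{network_module} (or character vector) whose LCC
#'   members define the Treatment module.
#' @param dsd_k random-walk length for the DSD (default 5).
#' @param n_modules random connected modules per null pool (default 500).
#' @param seed integer seed, or \code{NULL}.
#' @param dm optional precomputed \code{dsd_matrix} (must match \code{g});
#'   computed from \code{g} and \code{dsd_k} when absent.
#' @return data frame of class \code{score_table}, one row per vertex:
#'   \code{node}, \code{d_bar}, \code{dsd_bar}, \code{proximity_z},
#'   \code{selectivity_z}, \code{rank_p}, \code{rank_s},
#'   \code{combined_rank}, ordered by combined rank.
#' @export
prioritize <- function(g, genotype, treatment, dsd_k = 5L, n_modules = 500L,
                       seed = NULL, dm = NULL) {
  .assert_graph(g)
  gset <- .module_members(genotype)
  tset <- .module_members(treatment)
  if (length(gset) == 0L || length(tset) == 0L) {
    stop("both modules must be nonempty")
  }
  .assert_in_graph(g, gset, "genotype")
  .assert_in_graph(g, tset, "treatment")
  nodes <- sort(.node_names(g))

  D <- igraph::distances(g)[nodes, nodes]
  if (is.null(dm)) dm <- dsd_matrix(he_matrix(g, k = dsd_k))
  Ddsd <- dm$d[nodes, nodes]

  d_bar <- rowMeans(D[, gset, drop = FALSE])
  dsd_bar <- rowMeans(Ddsd[, tset, drop = FALSE])

  .with_seed(seed, {
    pool_g <- sample_connected_subgraph(g, length(gset), n_draws = n_modules)
    pool_t <- sample_connected_subgraph(g, length(tset), n_draws = n_modules)
    if (n_modules == 1L) {
      pool_g <- list(pool_g)
      pool_t <- list(pool_t)
      warning("n_modules = 1 gives an unstable null spread")
    }
    # membership matrices: node x module; statistic per (node, module) by
    # one matrix product
    Mg <- vapply(pool_g, function(m) as.numeric(nodes %in% m), numeric(length(nodes)))
    Mt <- vapply(pool_t, function(m) as.numeric(nodes %in% m), numeric(length(nodes)))
    stat_g <- (D %*% Mg) / length(gset)
    stat_t <- (Ddsd %*% Mt) / length(tset)
    mu_p <- rowMeans(stat_g)
    sd_p <- apply(stat_g, 1L, sd)
    mu_s <- rowMeans(stat_t)
    sd_s <- apply(stat_t, 1L, sd)
    sd_p[is.na(sd_p)] <- 0  # single-module pools have no spread
    sd_s[is.na(sd_s)] <- 0
    prox_z <- ifelse(sd_p > 0, (d_bar - mu_p) / sd_p,
                     ifelse(d_bar == mu_p, 0, sign(d_bar - mu_p) * Inf))
    sel_z <- ifelse(sd_s > 0, (dsd_bar - mu_s) / sd_s,
                    ifelse(dsd_bar == mu_s, 0, sign(dsd_bar - mu_s) * Inf))
    r_p <- rank_with_ties(prox_z, ascending = TRUE)
    r_s <- rank_with_ties(sel_z, ascending = TRUE)
    out <- data.frame(node = nodes, d_bar = d_bar, dsd_bar = dsd_bar,
                      proximity_z = prox_z, selectivity_z = sel_z,
                      rank_p = r_p, rank_s = r_s,
                      combined_rank = combined_rank(r_p, r_s),
                      row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(out$combined_rank, out$node), ]
    rownames(out) <- NULL
    class(out) <- c("score_table", "data.frame")
    out
  })
}

.module_members <- function(x) {
  if (inherits(x, "network_module")) x$lcc_members else unique(as.character(x))
}

#' Write a score table (optionally with merged baseline columns) as TSV
#'
#' @param table \code{score_table} data frame.
#' @param path output path.
#' @export
write_score_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}
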