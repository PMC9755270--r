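`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under `seed` when given, otherwise in the current RNG state.
# All exported samplers funnel through this so that seed = NULL composes
# inside a caller's own withr::with_seed() block.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.assert_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) stop(sprintf("`%s` must be an igraph object", arg))
  if (is.null(igraph::V(g)$name)) stop(sprintf("`%s` must have vertex names", arg))
  invisible(g)
}

.node_names <- function(g) igraph::V(g)$name

.assert_in_graph <- function(g, nodes, arg = "nodes") {
  missing <- setdiff(nodes, .node_names(g))
  if (length(missing) > 0L) {
    stop(sprintf("`%s` contains %d gene(s) absent from the graph (e.g. %s)",
                 arg, length(missing), paste(head(missing, 3L), collapse = ", ")))
  }
  invisible(nodes)
}

# 0-based adjacency list for the C++ sampler
.adj_list0 <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), function(v) as.integer(v) - 1L)
}
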