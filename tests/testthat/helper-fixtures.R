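# small named graphs used across the suite

path_graph <- function(n, nm = LETTERS[seq_len(n)]) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- nm
  g
}

ring_graph <- function(n, nm = letters[seq_len(n)]) {
  g <- igraph::make_ring(n)
  igraph::V(g)$name <- nm
  g
}

star_graph <- function(n_leaves, center = "X",
                       leaves = letters[seq_len(n_leaves)]) {
  g <- igraph::make_star(n_leaves + 1L, mode = "undirected", center = 1L)
  igraph::V(g)$name <- c(center, leaves)
  g
}

complete_graph <- function(n, nm = LETTERS[seq_len(n)]) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- nm
  g
}

random_connected_graph <- function(n, p = 0.25, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    g
  })
}

# 4-gene worked profile: ranking by z descending is g1, g2, g3, g4
toy_profile <- function() c(g1 = 3, g2 = 1, g3 = -1, g4 = -3)

# brute-force step-up BH oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Mann-Whitney pair-counting AUC oracle (ties count 1/2)
mw_auc_oracle <- function(scores, labels, higher_is_better = TRUE) {
  s <- if (higher_is_better) scores else -scores
  pos <- s[labels]
  neg <- s[!labels]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

empirical_tv_from_uniform <- function(g, size, n_draws, seed) {
  enum <- enumerate_connected_subgraphs(g, size)
  keys <- vapply(enum, paste, "", collapse = "-")
  draws <- sample_connected_subgraph(g, size, seed = seed, n_draws = n_draws)
  dk <- vapply(draws, paste, "", collapse = "-")
  stopifnot(all(dk %in% keys))
  emp <- table(factor(dk, levels = keys)) / n_draws
  0.5 * sum(abs(as.numeric(emp) - 1 / length(keys)))
}
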