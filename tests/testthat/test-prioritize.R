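test_that("average shortest path to a set matches hand values", {
  g <- path_graph(3)
  expect_equal(avg_shortest_path_to_set(g, "A", c("B", "C")), 1.5)
  expect_equal(avg_shortest_path_to_set(g, "A", "A"), 0)
  st <- star_graph(4)
  expect_equal(avg_shortest_path_to_set(st, "X", letters[1:4]), 1.0)
  expect_error(avg_shortest_path_to_set(g, "A", character(0)), "nonempty")
})

test_that("null distributions are seeded, sized and degenerate when forced", {
  g <- random_connected_graph(20, p = 0.25, seed = 14)
  n1 <- null_distribution(g, "avg_shortest_path", "n001", module_size = 4,
                          n_modules = 50, seed = 7)
  n2 <- null_distribution(g, "avg_shortest_path", "n001", module_size = 4,
                          n_modules = 50, seed = 7)
  expect_identical(n1$samples, n2$samples)
  expect_length(n1$samples, 50)
  expect_gt(n1$sigma, 0)

  expect_warning(
    deg <- null_distribution(g, "avg_shortest_path", "n001",
                             module_size = igraph::vcount(g), n_modules = 5,
                             seed = 1),
    NA)  # whole-graph modules: all samples equal
  expect_equal(deg$sigma, 0)

  dm <- dsd_matrix(he_matrix(g, k = 3))
  nd <- null_distribution(g, "avg_dsd", "n001", module_size = 4,
                          n_modules = 50, seed = 7, dm = dm)
  expect_length(nd$samples, 50)
  expect_error(null_distribution(g, "avg_dsd", "n001", module_size = 4,
                                 n_modules = 10, seed = 1), "dsd_matrix")
})

test_that("singleton null modules on a cycle average to the mean ring distance", {
  g <- ring_graph(6)
  n <- null_distribution(g, "avg_shortest_path", "a", module_size = 1,
                         n_modules = 2000, seed = 3)
  # distances from any vertex of C6: 0,1,1,2,2,3 -> mean 1.5
  expect_lt(abs(n$mu - 1.5), 0.05)
})

test_that("proximity and selectivity are direct Z-score substitutions", {
  null <- structure(list(mu = 3, sigma = 0.5), class = "null_distribution")
  expect_equal(proximity_score(2.0, null), -2.0)
  expect_equal(proximity_score(3.0, null), 0)
  expect_equal(proximity_score(4.0, null), 2.0)
  expect_equal(selectivity_score(3 - 2 * 0.5, null), -2.0)
  degen <- structure(list(mu = 3, sigma = 0), class = "null_distribution")
  expect_equal(proximity_score(3, degen), 0)
  expect_warning(z <- proximity_score(4, degen), "sentinel")
  expect_identical(z, Inf)
})

test_that("ranking uses average ties and the orientation flag", {
  expect_equal(rank_with_ties(c(0.1, 0.3, 0.2)), c(1, 3, 2))
  expect_equal(rank_with_ties(c(0.1, 0.1, 0.5)), c(1.5, 1.5, 3))
  expect_equal(rank_with_ties(c(0.1, 0.3, 0.2), ascending = FALSE), c(3, 1, 2))
  expect_error(rank_with_ties(c(0.1, NA)), "NA")
})

test_that("the combined rank is the geometric mean of the two ranks", {
  expect_equal(combined_rank(1, 4), 2)
  expect_equal(combined_rank(7, 7), 7)
  expect_equal(combined_rank(2, 8), combined_rank(8, 2))
  expect_error(combined_rank(0, 3), "positive")
})

test_that("prioritize produces a complete, reproducible, consistent table", {
  g <- generate_graph(100, model = "scale_free", seed = 31)
  genotype <- sample_connected_subgraph(g, 8, seed = 32)
  treatment <- sample_connected_subgraph(g, 6, seed = 33)
  tab <- prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 100, seed = 34)
  expect_setequal(tab$node, igraph::V(g)$name)
  expect_equal(tab$combined_rank^2, tab$rank_p * tab$rank_s)
  expect_true(all(tab$rank_p >= 1 & tab$rank_p <= nrow(tab)))
  tab2 <- prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 100, seed = 34)
  expect_identical(tab, tab2)

  expect_warning(prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 1,
                            seed = 1), "unstable")
})

test_that("genotype members are more proximal than the background", {
  g <- generate_graph(100, model = "scale_free", seed = 31)
  genotype <- sample_connected_subgraph(g, 8, seed = 32)
  treatment <- sample_connected_subgraph(g, 6, seed = 33)
  tab <- prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 100, seed = 34)
  inside <- tab$proximity_z[tab$node %in% genotype]
  outside <- tab$proximity_z[!(tab$node %in% genotype)]
  expect_lt(wilcox.test(inside, outside, alternative = "less")$p.value, 0.01)
})

test_that("the shared null pool equals a per-node null at the same seed", {
  g <- random_connected_graph(30, p = 0.15, seed = 41)
  genotype <- sample_connected_subgraph(g, 5, seed = 42)
  treatment <- sample_connected_subgraph(g, 4, seed = 43)
  tab <- prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 80, seed = 44)
  node <- tab$node[7]
  null <- null_distribution(g, "avg_shortest_path", node,
                            module_size = length(genotype), n_modules = 80,
                            seed = 44)
  d_bar <- avg_shortest_path_to_set(g, node, genotype)
  expect_equal(tab$proximity_z[tab$node == node],
               proximity_score(d_bar, null))
})

test_that("score tables are invariant to vertex relabeling up to the label map", {
  g <- random_connected_graph(25, p = 0.2, seed = 51)
  genotype <- sample_connected_subgraph(g, 5, seed = 52)
  treatment <- sample_connected_subgraph(g, 4, seed = 53)
  tab <- prioritize(g, genotype, treatment, dsd_k = 3, n_modules = 60, seed = 54)

  relabel <- setNames(sprintf("x%03d", seq_len(igraph::vcount(g))),
                      sort(igraph::V(g)$name))
  g2 <- g
  igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  tab2 <- prioritize(g2, unname(relabel[genotype]), unname(relabel[treatment]),
                     dsd_k = 3, n_modules = 60, seed = 54)
  m <- match(unname(relabel[tab$node]), tab2$node)
  expect_equal(tab2$d_bar[m], tab$d_bar)
  expect_equal(tab2$dsd_bar[m], tab$dsd_bar)
  # the null pools are drawn over relabeled vertices in the same index
  # order, so Z-scores and ranks carry over exactly
  expect_equal(tab2$proximity_z[m], tab$proximity_z)
  expect_equal(tab2$combined_rank[m], tab$combined_rank)
})

test_that("score tables round-trip through TSV", {
  g <- random_connected_graph(20, p = 0.25, seed = 61)
  tab <- prioritize(g, sample_connected_subgraph(g, 4, seed = 62),
                    sample_connected_subgraph(g, 3, seed = 63),
                    dsd_k = 2, n_modules = 40, seed = 64)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, f)
  tab2 <- read_score_table(f)
  expect_equal(tab2$combined_rank, tab$combined_rank, tolerance = 1e-10)
})
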