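test_that("complete graphs force a degenerate LCC null (sigma = 0 sentinel)", {
  g <- complete_graph(5)
  expect_warning(st <- lcc_significance(g, c("A", "B", "C"), n_samples = 50, seed = 1),
                 "sigma = 0")
  expect_equal(st$s_lcc, 3L)
  expect_equal(st$mu, 3)
  expect_equal(st$sigma, 0)
  expect_equal(st$z, 0)
  expect_equal(st$p_empirical, 1)
})

test_that("a planted connected module is detected as significantly clustered", {
  g <- generate_graph(200, model = "scale_free", seed = 21)
  planted <- sample_connected_subgraph(g, 20, seed = 22)
  st <- lcc_significance(g, planted, n_samples = 300, seed = 23)
  expect_equal(st$s_lcc, 20L)
  expect_gt(st$z, 2)
  expect_lt(st$p_empirical, 0.05)
})

test_that("a scattered set can score below its degree-matched null mean", {
  # two triangles joined by an edge; A and E have degree 2, are not
  # adjacent, and most degree-2 pairs in the null ARE adjacent
  g <- igraph::graph_from_literal(A - B, B - C, A - C, D - E, E - F, D - F, C - D)
  st <- lcc_significance(g, c("A", "E"), n_samples = 400, seed = 3)
  expect_equal(st$s_lcc, 1L)
  expect_gt(st$mu, 1)
  expect_lt(st$z, 0)
})

test_that("p-values of zero exceedances are reported as bounded", {
  g <- generate_graph(200, model = "scale_free", seed = 21)
  planted <- sample_connected_subgraph(g, 20, seed = 22)
  st <- lcc_significance(g, planted, n_samples = 200, seed = 5)
  expect_equal(st$n_exceed, 0L)
  expect_match(st$p_label, "^< ")
})

test_that("on a degree-regular graph the degree-binned null equals uniform sampling", {
  g <- ring_graph(30, nm = sprintf("r%02d", 1:30))
  s <- c("r01", "r02", "r03", "r10", "r20")
  st <- lcc_significance(g, s, n_samples = 800, seed = 9)
  unif <- withr::with_seed(10, {
    vapply(seq_len(800), function(i) {
      rs <- sample(igraph::V(g)$name, length(s))
      sub <- igraph::induced_subgraph(g, rs)
      max(igraph::components(sub)$csize)
    }, 0)
  })
  expect_lt(abs(mean(st$null_sizes) - mean(unif)), 0.15)
})

test_that("build_module maps, takes the LCC and is order-stable", {
  g <- path_graph(5)
  m <- suppressMessages(build_module(g, c("A", "B", "D"), n_samples = 20, seed = 1))
  expect_identical(m$lcc_members, c("A", "B"))
  expect_identical(m$mapped_genes, c("A", "B", "D"))

  m2 <- suppressMessages(build_module(g, c("D", "B", "A"), n_samples = 20, seed = 1))
  expect_identical(m$lcc_members, m2$lcc_members)
  expect_identical(m$stats$z, m2$stats$z)

  m3 <- suppressWarnings(  # all-degree-2 template forces a constant null
    suppressMessages(build_module(g, c("B", "C", "D"), n_samples = 20, seed = 1)))
  expect_identical(m3$lcc_members, c("B", "C", "D"))

  expect_error(suppressMessages(build_module(g, c("Z1", "Z2"))), "none of the")
})

test_that("fold-change gating overrides significance", {
  withr::with_seed(1, {
    n <- 10
    expr <- matrix(rnorm(50 * 2 * n, sd = 0.05), nrow = 50,
                   dimnames = list(sprintf("gene%02d", 1:50),
                                   c(sprintf("a%02d", 1:n), sprintf("b%02d", 1:n))))
    expr["gene01", 1:n] <- expr["gene01", 1:n] + 1  # 2-fold, highly significant
  })
  de <- differential_expression(expr, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10),
                                fc_threshold = 2.5, alpha = 0.05)
  row <- de[de$gene == "gene01", ]
  expect_lt(row$p_adj, 0.05)
  expect_equal(row$direction, "none")
  de2 <- differential_expression(expr, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10),
                                 fc_threshold = 1.8, alpha = 0.05)
  expect_equal(de2[de2$gene == "gene01", "direction"], "up")
})

test_that("null data yield roughly nominal raw type-I error", {
  fracs <- vapply(1:8, function(seed) {
    expr <- withr::with_seed(seed, {
      matrix(rnorm(400 * 20), nrow = 400,
             dimnames = list(sprintf("g%03d", 1:400),
                             c(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))))
    })
    de <- differential_expression(expr, sprintf("a%02d", 1:10),
                                  sprintf("b%02d", 1:10))
    mean(de$p < 0.05)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("a strong planted shift is recovered with the right direction", {
  expr <- withr::with_seed(2, {
    matrix(rnorm(100 * 40, mean = 7, sd = 0.3), nrow = 100,
           dimnames = list(sprintf("g%03d", 1:100),
                           c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20))))
  })
  expr["g001", 1:20] <- expr["g001", 1:20] + 2  # planted 4-fold up-shift
  de <- differential_expression(expr, sprintf("a%02d", 1:20), sprintf("b%02d", 1:20),
                                fc_threshold = 2.5)
  expect_equal(de[de$gene == "g001", "direction"], "up")
})

test_that("constant genes never reach significance and pairing is validated", {
  expr <- matrix(1, nrow = 2, ncol = 6,
                 dimnames = list(c("flat", "flat2"),
                                 c("a1", "a2", "a3", "b1", "b2", "b3")))
  de <- differential_expression(expr, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_true(all(de$p == 1))
  expect_true(all(de$direction == "none"))
  expect_error(
    differential_expression(expr, c("a1", "a2"), c("b1", "b2", "b3"), paired = TRUE),
    "paired")
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  withr::with_seed(4, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p))
      expect_true(all(adj >= p & adj <= 1))
      expect_false(is.unsorted(adj[order(p)]))
    }
  })
})

test_that("signatures derive from direction labels and merge by union", {
  de <- data.frame(gene = sprintf("g%02d", 1:10),
                   direction = c("up", "up", rep("down", 3), rep("none", 5)),
                   stringsAsFactors = FALSE)
  sig <- derive_signature(de)
  expect_length(sig$up, 2)
  expect_length(sig$down, 3)
  expect_length(intersect(sig$up, sig$down), 0)

  a <- gene_signature(c("A", "B"), c("C"))
  b <- gene_signature(c("D"), c("E"))
  m <- merge_signatures(a, b)
  expect_identical(m$up, c("A", "B", "D"))
  expect_identical(m$down, c("C", "E"))
  expect_identical(merge_signatures(a, a), a)

  conflicted <- gene_signature("C", "F")  # C up here, down in a
  expect_message(mc <- merge_signatures(a, conflicted), "dropped")
  expect_false("C" %in% c(mc$up, mc$down))
  expect_error(gene_signature(c("A"), c("A")), "disjoint")
})
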