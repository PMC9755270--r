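test_that("generated graphs are connected, named and seed-exact", {
  g <- generate_graph(500, model = "scale_free", seed = 101)
  expect_true(igraph::is_connected(g))
  deg <- igraph::degree(g)
  expect_gt(max(deg), 5 * median(deg))  # heavy-tailed degrees

  g2 <- generate_graph(500, model = "scale_free", seed = 101)
  expect_true(igraph::identical_graphs(g, g2))

  expect_message(ger <- generate_graph(80, model = "erdos_renyi",
                                       params = list(p = 0.02), seed = 102),
                 "largest component")
  expect_true(igraph::is_connected(ger))

  gsw <- generate_graph(60, model = "small_world", seed = 103)
  expect_true(igraph::is_connected(gsw))
  expect_error(generate_graph(5, seed = 1), ">= 10")
})

test_that("planted triads are connected with true targets outside the modules", {
  g <- generate_graph(300, model = "scale_free", seed = 111)
  tr <- plant_triad(g, seed = 112)
  for (set in list(tr$genotype_genes, tr$treatment_targets,
                   c(tr$response_up, tr$response_down))) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(g, set)))
  }
  expect_length(tr$true_targets, 5L)
  expect_length(intersect(tr$true_targets,
                          c(tr$genotype_genes, tr$treatment_targets)), 0L)
  # each true target touches the genotype set (one-hop construction)
  for (t in tr$true_targets) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, t)]
    expect_gt(length(intersect(nb, tr$genotype_genes)), 0L)
  }
  tr0 <- plant_triad(g, n_true_targets = 0, seed = 113)
  expect_length(tr0$true_targets, 0L)
})

test_that("true targets are more proximal than the typical node", {
  g <- generate_graph(300, model = "scale_free", seed = 111)
  tr <- plant_triad(g, seed = 112)
  d <- igraph::distances(g)
  d_bar <- rowMeans(d[, tr$genotype_genes])
  expect_lt(mean(d_bar[tr$true_targets]), median(d_bar))
})

test_that("expression generation is seed-exact and reverses the planted signature", {
  g <- generate_graph(200, model = "scale_free", seed = 121)
  tr <- plant_triad(g, seed = 122)
  ex <- generate_expression(tr, seed = 123)
  ex2 <- generate_expression(tr, seed = 123)
  expect_identical(ex, ex2)
  expect_equal(dim(ex$expr), c(igraph::vcount(g), 40L))

  groups <- ex$groups
  post <- groups$sample_id[groups$group == "post"]
  pre <- groups$sample_id[groups$group == "pre"]
  de <- differential_expression(ex$expr, post, pre, fc_threshold = 1.8,
                                paired = TRUE)
  sig <- derive_signature(de)
  expect_gte(length(intersect(sig$up, tr$response_up)) / length(tr$response_up), 0.95)
  expect_gte(length(intersect(sig$down, tr$response_down)) / length(tr$response_down), 0.95)
  expect_error(generate_expression(tr, n_per_group = 2), ">= 3")
})

test_that("a null expression matrix yields roughly nominal false-positive rates", {
  g <- generate_graph(150, model = "scale_free", seed = 131)
  tr <- plant_triad(g, seed = 132)
  fracs <- vapply(1:6, function(s) {
    ex <- generate_expression(tr, effect_log2fc = 0, seed = 200 + s)
    de <- differential_expression(ex$expr, ex$groups$sample_id[ex$groups$group == "post"],
                                  ex$groups$sample_id[ex$groups$group == "pre"],
                                  paired = TRUE)
    mean(de$p < 0.05)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("perturbation profiles revert the signature only when planted to", {
  g <- generate_graph(200, model = "scale_free", seed = 141)
  tr <- plant_triad(g, seed = 142)
  pt <- generate_perturbations(tr, seed = 143)
  expect_identical(pt, generate_perturbations(tr, seed = 143))
  sig <- gene_signature(tr$response_up, tr$response_down)

  rev_ids <- pt$metadata$experiment_id[grepl("rev", pt$metadata$compound_id)]
  for (eid in rev_ids[1:3]) {
    expect_lt(wtcs(pt$profiles[eid, ], sig)$wtcs, 0)
  }

  results <- wtcs_scan(pt$profiles, sig, n_perm = 300, seed = 144)
  targets <- select_treatment_targets(
    results, setNames(pt$metadata$compound_id, pt$metadata$experiment_id),
    pt$target_map)
  expect_identical(targets, tr$treatment_targets)
})

test_that("scenario simulation is reproducible and serializes completely", {
  sc <- simulate_scenario(n = 120, n_per_group = 5, n_neutral = 10, seed = 7)
  sc2 <- simulate_scenario(n = 120, n_per_group = 5, n_neutral = 10, seed = 7)
  expect_identical(sc$genotype_genes, sc2$genotype_genes)
  expect_identical(sc$expression$expr, sc2$expression$expr)
  expect_identical(sc$perturbations$profiles, sc2$perturbations$profiles)

  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "edges.tsv", "genotype_genes.txt", "treatment_targets.txt",
    "true_targets.txt", "response_signature.gmt", "expression.tsv",
    "sample_groups.tsv", "perturbations.tsv", "perturbation_meta.tsv",
    "compound_targets.tsv", "manifest.json")))))

  g2 <- read_edge_list(file.path(dir, "edges.tsv"))
  expect_equal(igraph::ecount(g2), igraph::ecount(sc$graph))
  expect_identical(read_gene_set(file.path(dir, "genotype_genes.txt")),
                   sc$genotype_genes)
  sig <- read_gmt(file.path(dir, "response_signature.gmt"))
  expect_identical(sig$response_up, sc$response_up)
  pt <- read_perturbations(file.path(dir, "perturbations.tsv"))
  expect_equal(pt, sc$perturbations$profiles, tolerance = 1e-10)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 7)
})
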