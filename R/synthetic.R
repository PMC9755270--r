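#' Generate a random connected graph
#'
#' Graph models emulating interactome-like topology.  The default
#' scale-free (preferential attachment) model mimics the heavy-tailed
#' degree distribution of protein-protein interaction networks; the
#' largest connected component is retained so downstream distance and
#' diffusion computations are always defined.
#'
#' @param n number of vertices before LCC extraction (>= 10).
#' @param model \code{"scale_free"}, \code{"small_world"} or
#'   \code{"erdos_renyi"}.
#' @param params model parameters: \code{m} (edges per new vertex,
#'   scale-free, default 2); \code{nei} and \code{p_rewire} (small-world,
#'   defaults 2 and 0.05); \code{p} (edge probability, Erdos-Renyi,
#'   default \code{2 log(n) / n}).
#' @param seed integer seed, or \code{NULL}.
#' @return connected simple igraph graph with vertex names
#'   \code{"g0001"}, \code{"g0002"}, ...
#' @export
generate_graph <- function(n, model = c("scale_free", "small_world", "erdos_renyi"),
                           params = list(), seed = NULL) {
  model <- match.arg(model)
  if (n < 10L) stop("n must be >= 10")
  .with_seed(seed, {
    g <- switch(model,
      scale_free = igraph::sample_pa(n, m = params$m %||% 2L, directed = FALSE),
      small_world = igraph::sample_smallworld(1L, n, params$nei %||% 2L,
                                              params$p_rewire %||% 0.05),
      erdos_renyi = igraph::sample_gnp(n, params$p %||% (2 * log(n) / n))
    )
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(igraph::vcount(g)))
    lcc <- largest_component(g)
    if (igraph::vcount(lcc) < n) {
      message(sprintf("retained largest component: %d of %d vertices",
                      igraph::vcount(lcc), n))
    }
    lcc
  })
}

#' Plant a module triad with known true targets on a graph
#'
#' Draws the Genotype and Treatment gene sets as connected subgraphs
#' (approximately uniformly), draws a connected Response gene set with
#' up/down labels, and plants \code{n_true_targets} "true targets":
#' vertices outside both modules chosen from the one-hop neighborhood of
#' the Genotype set (topologically relevant) with the lowest average DSD
#' to the Treatment set (functionally similar).  By construction the
#' true targets satisfy both ranking hypotheses simultaneously, while
#' module members themselves excel on only one axis each - which is what
#' makes combined-rank recovery a meaningful end-to-end check.
#'
#' @param g connected igraph graph with vertex names.
#' @param genotype_size,treatment_size,response_size module sizes.
#' @param n_true_targets number of true targets to plant (0 allowed).
#' @param dsd_k walk length for the DSD used during planting (default 5).
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{graph}, \code{genotype_genes},
#'   \code{treatment_targets}, \code{response_up}, \code{response_down},
#'   \code{true_targets}, \code{dsd_k} and \code{params}.
#' @export
plant_triad <- function(g, genotype_size = 15L, treatment_size = 10L,
                        response_size = 25L, n_true_targets = 5L,
                        dsd_k = 5L, seed = NULL) {
  .assert_graph(g)
  n <- igraph::vcount(g)
  if (genotype_size + treatment_size >= n) stop("module sizes infeasible for this graph")
  .with_seed(seed, {
    genotype <- sample_connected_subgraph(g, genotype_size)
    treatment <- sample_connected_subgraph(g, treatment_size)
    for (try in seq_len(50L)) {
      if (length(intersect(genotype, treatment)) <= 2L) break
      treatment <- sample_connected_subgraph(g, treatment_size)
    }
    response <- sample_connected_subgraph(g, response_size)
    up <- sort(sample(response, ceiling(response_size / 2)))
    down <- sort(setdiff(response, up))
    true_targets <- character(0L)
    if (n_true_targets > 0L) {
      nbrs <- unique(unlist(igraph::adjacent_vertices(g, genotype), use.names = FALSE))
      cand <- setdiff(.node_names(g)[nbrs], union(genotype, treatment))
      if (length(cand) < n_true_targets) {
        stop("genotype neighborhood too small to plant true targets; use larger modules")
      }
      # candidates satisfying both hypotheses at once: topologically close
      # to the genotype set AND diffusion-similar to the treatment set.
      # Raw distances are confounded by degree (hubs are close to every
      # module), so candidates are screened by the same null-normalized
      # statistics the framework ranks with, using a small pool of random
      # connected modules per size; the selection rule is part of the
      # recorded construction.
      dm <- dsd_matrix(he_matrix(g, k = dsd_k))
      n_pool <- 150L
      pool_g <- sample_connected_subgraph(g, length(genotype), n_draws = n_pool)
      pool_t <- sample_connected_subgraph(g, length(treatment), n_draws = n_pool)
      D <- igraph::distances(g, v = cand)
      z_of <- function(obs, stat_mat) {
        mu <- rowMeans(stat_mat)
        sdev <- apply(stat_mat, 1L, sd)
        ifelse(sdev > 0, (obs - mu) / sdev, 0)
      }
      stat_g <- vapply(pool_g, function(m) rowMeans(D[, m, drop = FALSE]),
                       numeric(length(cand)))
      stat_t <- vapply(pool_t, function(m) rowMeans(dm$d[cand, m, drop = FALSE]),
                       numeric(length(cand)))
      z_prox <- z_of(rowMeans(D[, genotype, drop = FALSE]), stat_g)
      z_sel <- z_of(rowMeans(dm$d[cand, treatment, drop = FALSE]), stat_t)
      score <- rank(z_prox, ties.method = "average") *
        rank(z_sel, ties.method = "average")
      true_targets <- sort(cand[order(score, cand)][seq_len(n_true_targets)])
    }
    list(graph = g,
         genotype_genes = sort(genotype),
         treatment_targets = sort(treatment),
         response_up = up,
         response_down = down,
         true_targets = true_targets,
         dsd_k = as.integer(dsd_k),
         params = list(genotype_size = genotype_size,
                       treatment_size = treatment_size,
                       response_size = response_size,
                       n_true_targets = n_true_targets))
  })
}

#' Generate a paired pre/post expression matrix with a reverted signature
#'
#' Emulates responder pre-/post-treatment transcriptomes on the log2
#' scale: every gene draws a baseline level of N(7, 1); planted
#' response-up genes gain \code{+effect_log2fc} in post-treatment samples
#' (they are up-regulated after successful treatment) and response-down
#' genes lose the same amount; all other genes are null.  Per-sample
#' Gaussian noise of sd \code{noise_sd} is added throughout.  Samples are
#' paired by subject.
#'
#' @param scenario triad list from \code{\link{plant_triad}}.
#' @param n_per_group subjects (>= 3); yields pre_i / post_i column pairs.
#' @param effect_log2fc planted log2 effect size (default 2, i.e. a
#'   4-fold linear shift).
#' @param noise_sd per-sample Gaussian noise sd (default 0.3).
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{expr} (genes x samples matrix, log2 scale) and
#'   \code{groups} (data frame: \code{sample_id}, \code{group},
#'   \code{pair_id}).
#' @export
generate_expression <- function(scenario, n_per_group = 20L,
                                effect_log2fc = 2, noise_sd = 0.3,
                                seed = NULL) {
  if (n_per_group < 3L) stop("n_per_group must be >= 3")
  genes <- sort(.node_names(scenario$graph))
  .with_seed(seed, {
    baseline <- rnorm(length(genes), mean = 7, sd = 1)
    names(baseline) <- genes
    pre_ids <- sprintf("pre_%02d", seq_len(n_per_group))
    post_ids <- sprintf("post_%02d", seq_len(n_per_group))
    expr <- matrix(rnorm(length(genes) * 2L * n_per_group, sd = noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, c(pre_ids, post_ids)))
    expr <- expr + baseline
    expr[scenario$response_up, post_ids] <-
      expr[scenario$response_up, post_ids] + effect_log2fc
    expr[scenario$response_down, post_ids] <-
      expr[scenario$response_down, post_ids] - effect_log2fc
    groups <- data.frame(
      sample_id = c(pre_ids, post_ids),
      group = rep(c("pre", "post"), each = n_per_group),
      pair_id = rep(sprintf("subj_%02d", seq_len(n_per_group)), 2L),
      stringsAsFactors = FALSE)
    list(expr = expr, groups = groups)
  })
}

#' Generate perturbation profiles with planted signature reversal
#'
#' Emulates level-5-style per-gene z-score profiles over a high-fidelity
#' gene universe (all graph vertices).  Reverting experiments push the
#' planted response-up genes to strongly negative z and response-down
#' genes to strongly positive z (signature reversal); neutral experiments
#' are i.i.d. standard normal.  Compounds of reverting experiments
#' partition the planted Treatment targets (so the union over kept
#' compounds is the full planted set); neutral compounds map to decoy
#' targets outside the Treatment set.
#'
#' @param scenario triad list from \code{\link{plant_triad}}.
#' @param n_reverting,n_neutral experiment counts.
#' @param signal_strength |mean z| of the reverted signature genes
#'   (default 4).
#' @param n_reverting_compounds compounds sharing the reverting
#'   experiments (default 4, capped at both \code{n_reverting} and the
#'   number of planted targets).
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{profiles} (experiments x genes matrix),
#'   \code{metadata} (data frame: \code{experiment_id},
#'   \code{compound_id}, \code{cell_line}) and \code{target_map} (named
#'   list: compound -> targets).
#' @export
generate_perturbations <- function(scenario, n_reverting = 8L,
                                   n_neutral = 40L, signal_strength = 4,
                                   n_reverting_compounds = 4L, seed = NULL) {
  genes <- sort(.node_names(scenario$graph))
  n_rc <- max(1L, min(n_reverting_compounds, n_reverting,
                      length(scenario$treatment_targets)))
  .with_seed(seed, {
    n_exp <- n_reverting + n_neutral
    ids <- sprintf("exp_%03d", seq_len(n_exp))
    profiles <- matrix(rnorm(n_exp * length(genes)), nrow = n_exp,
                       dimnames = list(ids, genes))
    rev_ids <- ids[seq_len(n_reverting)]
    if (n_reverting > 0L) {
      profiles[rev_ids, scenario$response_up] <-
        profiles[rev_ids, scenario$response_up] - signal_strength
      profiles[rev_ids, scenario$response_down] <-
        profiles[rev_ids, scenario$response_down] + signal_strength
    }
    rev_cpds <- sprintf("cpd_rev_%02d", seq_len(n_rc))
    neutral_cpds <- sprintf("cpd_neu_%02d", seq_len(max(1L, ceiling(n_neutral / 2L))))
    compound_of <- c(rep(rev_cpds, length.out = n_reverting),
                     rep(neutral_cpds, length.out = n_neutral))
    metadata <- data.frame(experiment_id = ids,
                           compound_id = compound_of,
                           cell_line = "SYN1",
                           stringsAsFactors = FALSE)
    # partition planted targets over reverting compounds: union = full set
    split_targets <- split(scenario$treatment_targets,
                           rep(seq_len(n_rc),
                               length.out = length(scenario$treatment_targets)))
    target_map <- setNames(split_targets, rev_cpds)
    decoys <- setdiff(genes, scenario$treatment_targets)
    for (cp in neutral_cpds) {
      target_map[[cp]] <- sort(sample(decoys, min(3L, length(decoys))))
    }
    list(profiles = profiles, metadata = metadata, target_map = target_map)
  })
}

#' Build a complete synthetic scenario with planted ground truth
#'
#' Chains \code{\link{generate_graph}}, \code{\link{plant_triad}},
#' \code{\link{generate_expression}} and
#' \code{\link{generate_perturbations}} into a single seeded object
#' providing every input the pipeline consumes.  The defaults define the
#' "smoke scenario": a 300-vertex scale-free graph, Genotype/Treatment/
#' Response modules of 15/10/25 genes, and 5 planted true targets.
#'
#' @param n graph size (default 300).
#' @param genotype_size,treatment_size,response_size module sizes
#'   (defaults 15/10/25).
#' @param n_true_targets planted true targets (default 5).
#' @param model graph model (default scale-free).
#' @param dsd_k DSD walk length (default 5).
#' @param n_per_group expression subjects per group (default 20).
#' @param effect_log2fc,noise_sd expression effect and noise (defaults 2
#'   and 0.3).
#' @param n_reverting,n_neutral,signal_strength perturbation counts and
#'   signal (defaults 8, 40, 4).
#' @param seed integer seed (required: scenarios are reproducible by
#'   construction).
#' @return list of class \code{triad_scenario} combining the planted
#'   triad, \code{expression}, \code{perturbations} and all generator
#'   parameters under \code{$params}.
#' @export
simulate_scenario <- function(n = 300L, genotype_size = 15L,
                              treatment_size = 10L, response_size = 25L,
                              n_true_targets = 5L, model = "scale_free",
                              dsd_k = 5L, n_per_group = 20L,
                              effect_log2fc = 2, noise_sd = 0.3,
                              n_reverting = 8L, n_neutral = 40L,
                              signal_strength = 4, seed = 1L) {
  params <- list(n = n, genotype_size = genotype_size,
                 treatment_size = treatment_size,
                 response_size = response_size,
                 n_true_targets = n_true_targets, model = model,
                 dsd_k = dsd_k, n_per_group = n_per_group,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 n_reverting = n_reverting, n_neutral = n_neutral,
                 signal_strength = signal_strength, seed = seed)
  .with_seed(seed, {
    g <- generate_graph(n, model = model)
    triad <- plant_triad(g, genotype_size, treatment_size, response_size,
                         n_true_targets, dsd_k = dsd_k)
    expression <- generate_expression(triad, n_per_group = n_per_group,
                                      effect_log2fc = effect_log2fc,
                                      noise_sd = noise_sd)
    perturbations <- generate_perturbations(triad, n_reverting = n_reverting,
                                            n_neutral = n_neutral,
                                            signal_strength = signal_strength)
    triad$params <- NULL  # superseded by the full parameter record below
    structure(c(triad,
                list(expression = expression,
                     perturbations = perturbations,
                     params = params)),
              class = "triad_scenario")
  })
}

#' Serialize a scenario as a directory of standard input files
#'
#' Writes the edge list, gene sets (plain text and GMT), expression and
#' perturbation TSVs, compound-target map and a JSON manifest of all
#' generator parameters, i.e. exactly the files the rest of the package
#' reads.
#'
#' @param scenario \code{triad_scenario}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_edge_list(scenario$graph, fp("edges.tsv"))
  write_gene_set(scenario$genotype_genes, fp("genotype_genes.txt"))
  write_gene_set(scenario$treatment_targets, fp("treatment_targets.txt"))
  write_gene_set(scenario$true_targets, fp("true_targets.txt"))
  write_gmt(list(response_up = scenario$response_up,
                 response_down = scenario$response_down),
            fp("response_signature.gmt"))
  ex <- scenario$expression
  write.table(data.frame(gene = rownames(ex$expr), ex$expr,
                         check.names = FALSE, stringsAsFactors = FALSE),
              fp("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ex$groups, fp("sample_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pt <- scenario$perturbations
  write_perturbations(pt$profiles, fp("perturbations.tsv"))
  write.table(pt$metadata, fp("perturbation_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tm <- data.frame(compound_id = rep(names(pt$target_map),
                                     lengths(pt$target_map)),
                   target = unlist(pt$target_map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(tm, fp("compound_targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(scenario$params, fp("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
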