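#' Significance of a gene set's largest connected component
#'
#' Measures how exceptionally interconnected a gene set is on the graph.
#' The observed statistic is the size \eqn{S_{LCC}} of the largest
#' connected component induced by the set.  The null model draws
#' \code{n_samples} degree-matched random sets of the same size
#' (\code{\link{sample_degree_matched_set}}), reduces each to its LCC
#' size, and reports
#' \deqn{Z_{LCC} = (S_{LCC} - \mu_{LCC}) / \sigma_{LCC}}
#' together with the empirical p-value, the fraction of null draws whose
#' LCC size reaches at least \eqn{S_{LCC}}.  When no null draw reaches the
#' observed size the p-value is reported as bounded above by
#' \code{1/n_samples} (the raw exceedance count is always stored).
#'
#' @param g connected igraph graph with vertex names.
#' @param genes character vector of vertex names (subset of \code{V(g)}).
#' @param n_samples number of degree-matched null samples (conventionally
#'   10,000 for full-scale interactomes; reduce for small graphs).
#' @param seed integer seed, or \code{NULL}.
#' @return object of class \code{lcc_stats}: list with \code{s_lcc},
#'   \code{mu}, \code{sigma}, \code{z}, \code{p_empirical} (numeric,
#'   exceedances / n_samples), \code{p_label} (character, \code{"< 1/n"}
#'   style when the count is zero), \code{n_exceed}, \code{n_samples}.
#' @export
lcc_significance <- function(g, genes, n_samples = 1000L, seed = NULL) {
  .assert_graph(g)
  genes <- unique(as.character(genes))
  .assert_in_graph(g, genes, "genes")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  s_lcc <- .lcc_size(g, genes)
  null_sizes <- .with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      rs <- suppressMessages(sample_degree_matched_set(g, genes))
      .lcc_size(g, rs)
    }, 0L)
  })
  mu <- mean(null_sizes)
  sigma <- sd(null_sizes)
  if (n_samples == 1L) sigma <- 0
  n_exceed <- sum(null_sizes >= s_lcc)
  if (sigma == 0) {
    z <- if (s_lcc == mu) 0 else sign(s_lcc - mu) * Inf
    warning("null LCC sizes are constant (sigma = 0); z set to sentinel value")
  } else {
    z <- (s_lcc - mu) / sigma
  }
  p <- n_exceed / n_samples
  p_label <- if (n_exceed == 0L) sprintf("< %g", 1 / n_samples) else format(p)
  structure(list(s_lcc = s_lcc, mu = mu, sigma = sigma, z = z,
                 p_empirical = p, p_label = p_label,
                 n_exceed = n_exceed, n_samples = n_samples,
                 null_sizes = null_sizes),
            class = "lcc_stats")
}

.lcc_size <- function(g, genes) {
  if (length(genes) == 0L) return(0L)
  sub <- igraph::induced_subgraph(g, genes)
  if (igraph::vcount(sub) == 0L) return(0L)
  as.integer(max(igraph::components(sub)$csize))
}

#' @export
print.lcc_stats <- function(x, ...) {
  cat(sprintf("LCC significance: S_LCC = %d, mu = %.3f, sigma = %.3f, Z = %.3f, p %s (%d samples)\n",
              x$s_lcc, x$mu, x$sigma, x$z,
              if (x$n_exceed == 0L) x$p_label else sprintf("= %s", x$p_label),
              x$n_samples))
  invisible(x)
}

#' Build a network module from a gene set
#'
#' Maps the genes to the graph, induces the subgraph, extracts its largest
#' connected component (the module), and attaches LCC-significance
#' statistics.  This is the common construction for Genotype, Response and
#' Treatment modules.
#'
#' @inheritParams lcc_significance
#' @param label free-text module label.
#' @return object of class \code{network_module}: list with \code{label},
#'   \code{input_genes}, \code{mapped_genes}, \code{unmapped_genes},
#'   \code{lcc_members} and \code{stats} (an \code{lcc_stats}).
#' @export
build_module <- function(g, genes, label = "module", n_samples = 1000L,
                         seed = NULL) {
  .assert_graph(g)
  genes <- unique(as.character(genes))
  mm <- suppressMessages(map_gene_set(g, genes))
  if (length(mm$mapped) == 0L) {
    stop(sprintf("module '%s': none of the %d input genes map to the graph",
                 label, length(genes)))
  }
  sub <- igraph::induced_subgraph(g, mm$mapped)
  lcc <- largest_component(sub)
  stats <- lcc_significance(g, mm$mapped, n_samples = n_samples, seed = seed)
  structure(list(label = label,
                 input_genes = sort(genes),
                 mapped_genes = mm$mapped,
                 unmapped_genes = mm$unmapped,
                 lcc_members = sort(.node_names(lcc)),
                 stats = stats),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat(sprintf("Network module '%s': %d input genes, %d mapped, LCC of %d\n",
              x$label, length(x$input_genes), length(x$mapped_genes),
              length(x$lcc_members)))
  print(x$stats)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input.  Thin validated wrapper over \code{stats::p.adjust}.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, each at least the raw value and at most 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must be finite and within [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sample comparison on a log2-scale expression matrix:
#' Welch's t-test (unpaired) or a paired t-test, with Benjamini-Hochberg
#' adjustment.  Fold change is computed as the difference of group means
#' on the log2 scale and reported as a linear fold change for
#' thresholding.  A gene is labelled \code{up}/\code{down} only when the
#' linear fold-change magnitude exceeds \code{fc_threshold} and the
#' adjusted p-value is below \code{alpha}; direction follows the sign of
#' the log fold change (group A relative to group B).  Genes constant
#' across all samples get p = 1 and are never significant.
#'
#' @param expr numeric matrix, genes x samples, log2 scale (set
#'   \code{log_scale = FALSE} for linear input, which is log2-transformed
#'   with a pseudo-count of 1).
#' @param group_a,group_b character vectors of column names; for
#'   \code{paired = TRUE} the i-th elements must come from the same
#'   subject.
#' @param fc_threshold linear fold-change threshold (e.g. 2.5 for
#'   case/control contrasts, 1.8 for pre/post-treatment contrasts).
#' @param alpha adjusted p-value threshold.
#' @param paired logical; paired t-test on matched columns.
#' @param log_scale logical; input already on log2 scale.
#' @return data frame (one row per gene): \code{gene}, \code{log2_fc},
#'   \code{fc} (linear magnitude), \code{p}, \code{p_adj},
#'   \code{direction} (\code{"up"}, \code{"down"} or \code{"none"}).
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    fc_threshold = 1.8, alpha = 0.05,
                                    paired = FALSE, log_scale = TRUE) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  missing_s <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing_s) > 0L) {
    stop(sprintf("sample id(s) not in expression matrix: %s",
                 paste(head(missing_s, 3L), collapse = ", ")))
  }
  if (paired && length(group_a) != length(group_b)) {
    stop("paired analysis requires equally sized, matched sample groups")
  }
  if (!paired && (length(group_a) < 2L || length(group_b) < 2L)) {
    stop("each group needs at least 2 samples")
  }
  if (!log_scale) expr <- log2(expr + 1)
  xa <- expr[, group_a, drop = FALSE]
  xb <- expr[, group_b, drop = FALSE]
  log2_fc <- rowMeans(xa) - rowMeans(xb)
  pvals <- vapply(seq_len(nrow(expr)), function(i) {
    a <- xa[i, ]
    b <- xb[i, ]
    if (paired) {
      d <- a - b
      if (sd(d) == 0) return(1)
      t.test(a, b, paired = TRUE)$p.value
    } else {
      if (sd(a) == 0 && sd(b) == 0) return(1)
      t.test(a, b, var.equal = FALSE)$p.value
    }
  }, 0)
  p_adj <- bh_adjust(pvals)
  fc <- 2^abs(log2_fc)
  direction <- ifelse(fc > fc_threshold & p_adj < alpha,
                      ifelse(log2_fc > 0, "up", "down"), "none")
  data.frame(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             log2_fc = log2_fc, fc = fc, p = pvals, p_adj = p_adj,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Construct an up/down gene signature
#'
#' @param up,down disjoint character vectors of gene symbols.
#' @return object of class \code{signature}.
#' @export
gene_signature <- function(up, down) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down)) > 0L) {
    stop("up and down sets must be disjoint")
  }
  structure(list(up = up, down = down), class = "signature")
}

#' Up/down signature from a differential-expression table
#'
#' @param de data frame as returned by
#'   \code{\link{differential_expression}}.
#' @return object of class \code{signature}: list with disjoint character
#'   vectors \code{up} and \code{down}.
#' @export
derive_signature <- function(de) {
  sig <- structure(list(up = sort(de$gene[de$direction == "up"]),
                        down = sort(de$gene[de$direction == "down"])),
                   class = "signature")
  stopifnot(length(intersect(sig$up, sig$down)) == 0L)
  sig
}

#' Merge two up/down signatures
#'
#' Componentwise union; a gene that is up-regulated in one signature and
#' down-regulated in the other is contradictory and is dropped from both
#' sets (reported via a message).
#'
#' @param a,b \code{signature} objects.
#' @return merged \code{signature}.
#' @export
merge_signatures <- function(a, b) {
  up <- union(a$up, b$up)
  down <- union(a$down, b$down)
  conflict <- intersect(up, down)
  if (length(conflict) > 0L) {
    message(sprintf("%d gene(s) up in one signature and down in the other; dropped: %s",
                    length(conflict), paste(head(conflict, 5L), collapse = ", ")))
    up <- setdiff(up, conflict)
    down <- setdiff(down, conflict)
  }
  structure(list(up = sort(up), down = sort(down)), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("Signature: %d up, %d down\n", length(x$up), length(x$down)))
  invisible(x)
}
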