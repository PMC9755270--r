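# Ranked-list layout shared by enrichment_score() and the permutation
# null: genes ordered by z descending, ties broken by gene symbol for
# determinism.
.es_ranking <- function(z, weight_exponent) {
  ord <- order(-z, names(z))
  list(genes = names(z)[ord], w = abs(z[ord])^weight_exponent,
       n = length(z))
}

# ES from hit positions within a precomputed ranking.  The running sum
# increments by |z|^w / sum(|z_query|^w) at hits and decrements by
# 1/(N - Nh) at misses; ES is the signed extremum of largest magnitude
# (ties between equal-magnitude positive and negative extrema resolve
# positive, the GSEA convention).  Only values adjacent to hits need
# inspection: between hits the running sum decreases monotonically.
.es_at_positions <- function(rk, pos) {
  nh <- length(pos)
  if (nh == 0L) stop("query does not intersect the profile universe")
  if (nh == rk$n) return(1)
  pos <- sort(pos)
  wq <- rk$w[pos]
  denom <- sum(wq)
  if (denom == 0) {
    warning("all query genes have zero |z|^w weight; enrichment score set to 0")
    return(0)
  }
  miss_step <- 1 / (rk$n - nh)
  cum_hit <- cumsum(wq) / denom
  misses_before <- pos - seq_len(nh)
  after <- cum_hit - misses_before * miss_step          # just after hit j
  before <- c(0, cum_hit[-nh]) - misses_before * miss_step  # just before hit j
  mx <- max(after, before, 0)
  mn <- min(after, before, 0)
  if (mx >= -mn) mx else mn
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum statistic of a query gene set against a
#' perturbation profile.  Genes are ranked by z descending (ties broken
#' by gene symbol); a hit at gene g adds \eqn{|z_g|^w / \sum_q |z_q|^w},
#' a miss subtracts \eqn{1/(N - N_h)}; the score is the signed extremum
#' of the running sum, in [-1, 1].  \code{weight_exponent = 0} gives the
#' classic unweighted Kolmogorov-Smirnov form.
#'
#' @param z named numeric vector of per-gene perturbation z-scores (the
#'   profile universe).
#' @param query character vector of query genes; must intersect the
#'   universe.
#' @param weight_exponent nonnegative weight exponent w (default 1).
#' @return numeric scalar in [-1, 1].
#' @export
enrichment_score <- function(z, query, weight_exponent = 1) {
  stopifnot(is.numeric(z), !is.null(names(z)))
  if (any(!is.finite(z))) stop("profile z-scores must be finite")
  rk <- .es_ranking(z, weight_exponent)
  pos <- which(rk$genes %in% query)
  .es_at_positions(rk, pos)
}

#' Weighted connectivity score of a profile against an up/down signature
#'
#' Combines the enrichment scores of the up- and down-query sets:
#' \deqn{WTCS = (ES_{up} - ES_{down})/2 \textrm{ if } sign(ES_{up}) \ne
#' sign(ES_{down}); \quad 0 \textrm{ otherwise.}}
#' Negative WTCS means the perturbation reverses the signature (up-query
#' genes pushed down and vice versa).
#'
#' @inheritParams enrichment_score
#' @param sig \code{signature} with components \code{up} and \code{down}.
#' @return list with \code{es_up}, \code{es_down}, \code{wtcs}.
#' @export
wtcs <- function(z, sig, weight_exponent = 1) {
  es_up <- enrichment_score(z, sig$up, weight_exponent)
  es_down <- enrichment_score(z, sig$down, weight_exponent)
  w <- if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
  list(es_up = es_up, es_down = es_down, wtcs = w)
}

#' WTCS with permutation p-values
#'
#' Assesses each enrichment score against a null built by drawing gene
#' sets of the same sizes uniformly from the profile universe
#' \code{n_perm} times.  The p-value is one-sided in the direction of the
#' observed score and, following the GSEA convention for signed
#' extremum statistics, is normalized by the same-sign portion of the
#' null: for a positive ES, the fraction of positive null scores at
#' least as large; for a negative ES, the fraction of negative null
#' scores at most as small; an ES of exactly 0 gets p = 1.  Under the
#' null this makes the p-values uniform on [0, 1].
#'
#' @inheritParams wtcs
#' @param n_perm number of uniform null gene-set draws (default 1000).
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{es_up}, \code{es_down}, \code{wtcs},
#'   \code{p_up}, \code{p_down}, \code{n_perm}.
#' @export
wtcs_significance <- function(z, sig, n_perm = 1000L, seed = NULL,
                              weight_exponent = 1) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  rk <- .es_ranking(z, weight_exponent)
  n_up <- sum(rk$genes %in% sig$up)
  n_down <- sum(rk$genes %in% sig$down)
  if (n_up == 0L || n_down == 0L) {
    stop("both query sets must intersect the profile universe")
  }
  if (n_up > rk$n || n_down > rk$n) stop("query larger than universe")
  obs <- wtcs(z, sig, weight_exponent)
  .with_seed(seed, {
    null_up <- vapply(seq_len(n_perm), function(i) {
      .es_at_positions(rk, sample.int(rk$n, n_up))
    }, 0)
    null_down <- vapply(seq_len(n_perm), function(i) {
      .es_at_positions(rk, sample.int(rk$n, n_down))
    }, 0)
    p_tail <- function(es_obs, null) {
      if (es_obs > 0) sum(null >= es_obs) / max(1L, sum(null > 0))
      else if (es_obs < 0) sum(null <= es_obs) / max(1L, sum(null < 0))
      else 1
    }
    c(obs, list(p_up = p_tail(obs$es_up, null_up),
                p_down = p_tail(obs$es_down, null_down),
                n_perm = as.integer(n_perm)))
  })
}

#' Score every experiment of a perturbation collection
#'
#' Runs \code{\link{wtcs_significance}} over the rows of an experiments x
#' genes z-score matrix.
#'
#' @param profiles numeric matrix, experiments (rows, named) x genes
#'   (columns, named); the column set is the profile universe.
#' @param sig \code{signature}.
#' @param n_perm permutations per experiment.
#' @param seed integer seed, or \code{NULL}; the whole scan is seeded
#'   once, so results are reproducible as a batch.
#' @param weight_exponent weight exponent for the enrichment score.
#' @return data frame: \code{experiment_id}, \code{es_up},
#'   \code{es_down}, \code{wtcs}, \code{p_up}, \code{p_down}.
#' @export
wtcs_scan <- function(profiles, sig, n_perm = 1000L, seed = NULL,
                      weight_exponent = 1) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            !is.null(colnames(profiles)))
  .with_seed(seed, {
    rows <- lapply(rownames(profiles), function(eid) {
      r <- wtcs_significance(profiles[eid, ], sig, n_perm = n_perm,
                             weight_exponent = weight_exponent)
      data.frame(experiment_id = eid, es_up = r$es_up, es_down = r$es_down,
                 wtcs = r$wtcs, p_up = r$p_up, p_down = r$p_down,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Derive the Treatment gene set from scored experiments
#'
#' Keeps experiments with \code{wtcs < 0} and both permutation p-values
#' below \code{alpha} (signature-reverting perturbations), maps their
#' compounds to protein targets, and returns the union of targets.
#' Compounds without an entry in the target map are reported and skipped.
#'
#' @param results data frame from \code{\link{wtcs_scan}} (needs columns
#'   \code{experiment_id}, \code{wtcs}, \code{p_up}, \code{p_down}).
#' @param experiment_compound named character vector mapping experiment
#'   id to compound id.
#' @param target_map named list mapping compound id to a character vector
#'   of target gene symbols.
#' @param alpha significance threshold (default 0.05).
#' @return sorted character vector of target gene symbols.
#' @export
select_treatment_targets <- function(results, experiment_compound, target_map,
                                     alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  keep <- results$wtcs < 0 & results$p_up < alpha & results$p_down < alpha
  kept_exp <- results$experiment_id[keep]
  compounds <- unique(unname(experiment_compound[kept_exp]))
  unmapped <- compounds[!(compounds %in% names(target_map))]
  if (length(unmapped) > 0L) {
    message(sprintf("%d compound(s) without target annotation skipped: %s",
                    length(unmapped), paste(head(unmapped, 5L), collapse = ", ")))
  }
  mapped <- intersect(compounds, names(target_map))
  sort(unique(unlist(target_map[mapped], use.names = FALSE)))
}

#' Read a perturbation z-score matrix and its metadata
#'
#' The matrix TSV has experiments as rows (first column
#' \code{experiment_id}) and genes as columns; the metadata TSV has
#' columns \code{experiment_id}, \code{compound_id}, \code{cell_line};
#' the target-map TSV has two columns, compound and target (one pair per
#' line).
#'
#' @param path file path.
#' @return \code{read_perturbations}: numeric matrix with experiment ids
#'   as rownames; \code{read_experiment_metadata}: data frame;
#'   \code{read_target_map}: named list of character vectors.
#' @export
read_perturbations <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_perturbations
#' @export
read_experiment_metadata <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_perturbations
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  split(df[[2L]], df[[1L]])
}

#' @rdname read_perturbations
#' @param profiles numeric matrix to write.
#' @export
write_perturbations <- function(profiles, path) {
  df <- data.frame(experiment_id = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
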