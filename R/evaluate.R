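#' Labeled ranking for target-recovery evaluation
#'
#' Wraps per-node scores, the positive (known-target) set, and the score
#' orientation.  The induced ordering breaks score ties by node name so
#' precision/recall at K are deterministic; threshold-based metrics (ROC,
#' AUPR) treat a tie group as a single threshold step.
#'
#' @param scores named numeric vector, one score per node.
#' @param positives character vector of positive nodes (must be scored).
#' @param higher_is_better logical orientation of the scores.
#' @return object of class \code{labeled_ranking}.
#' @export
labeled_ranking <- function(scores, positives, higher_is_better = TRUE) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (anyDuplicated(names(scores))) stop("duplicate node names in scores")
  if (any(is.na(scores))) stop("scores contain NA")
  positives <- unique(as.character(positives))
  missing <- setdiff(positives, names(scores))
  if (length(missing) > 0L) {
    stop(sprintf("positive node(s) not scored: %s", paste(head(missing, 3L), collapse = ", ")))
  }
  key <- if (higher_is_better) -scores else scores
  ord <- order(key, names(scores))
  structure(list(nodes = names(scores)[ord],
                 key = unname(key[ord]),  # ascending; ties = equal key
                 labels = names(scores)[ord] %in% positives,
                 n_pos = length(positives),
                 higher_is_better = higher_is_better),
            class = "labeled_ranking")
}

# cumulative TP/FP after each tie group (threshold sweep best-to-worst)
.tie_group_sweep <- function(r) {
  grp <- cumsum(!duplicated(r$key))
  tp <- cumsum(r$labels)
  fp <- cumsum(!r$labels)
  last <- which(!duplicated(grp, fromLast = TRUE))
  list(tp = tp[last], fp = fp[last])
}

#' ROC curve and area under it
#'
#' Sweeps the ranking threshold over tie groups, accumulating true- and
#' false-positive rates, and integrates by the trapezoidal rule.  With
#' average treatment of ties this equals the Mann-Whitney statistic
#' \eqn{U / (n_+ n_-)}.
#'
#' @param r \code{labeled_ranking} with at least one positive and one
#'   negative.
#' @return list with \code{curve} (data frame of \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
roc_auc <- function(r) {
  stopifnot(inherits(r, "labeled_ranking"))
  P <- sum(r$labels)
  N <- length(r$labels) - P
  if (P == 0L || N == 0L) stop("need at least one positive and one negative")
  sw <- .tie_group_sweep(r)
  tpr <- c(0, sw$tp / P)
  fpr <- c(0, sw$fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision/recall metrics and area under the PR curve
#'
#' Precision@K is the number of positives among the top K ranked nodes
#' divided by K (deterministic tie order by node name); recall@K divides
#' by the total number of positives.  The PR curve steps over tie groups
#' and the area uses step (right-continuous precision) interpolation,
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @param r \code{labeled_ranking}.
#' @param k_values integer vector of cutoffs, each at most the number of
#'   ranked nodes (default 500).
#' @return list with \code{curve} (data frame of \code{recall},
#'   \code{precision}), \code{aupr}, \code{precision_at} and
#'   \code{recall_at} (named by K).
#' @export
pr_metrics <- function(r, k_values = 500L) {
  stopifnot(inherits(r, "labeled_ranking"))
  n <- length(r$labels)
  if (any(k_values > n)) stop(sprintf("K exceeds the number of ranked nodes (%d)", n))
  P <- sum(r$labels)
  if (P == 0L) stop("need at least one positive")
  sw <- .tie_group_sweep(r)
  recall <- sw$tp / P
  precision <- sw$tp / (sw$tp + sw$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  cum_tp <- cumsum(r$labels)
  precision_at <- setNames(cum_tp[k_values] / k_values, k_values)
  recall_at <- setNames(cum_tp[k_values] / P, k_values)
  list(curve = data.frame(recall = recall, precision = precision),
       aupr = aupr, precision_at = precision_at, recall_at = recall_at)
}

#' Leave-one-in recovery of approved targets from DSD alone
#'
#' For each approved target t, ranks every other node by ascending DSD to
#' t with the remaining approved targets as positives, builds ROC and PR
#' curves, interpolates each onto a fixed evenly spaced grid, and
#' averages pointwise.  Quantifies whether knowing a single approved
#' target's diffusion profile suffices to recover the others.
#'
#' @param dm \code{dsd_matrix}.
#' @param approved character vector of at least 2 approved-target nodes
#'   present in \code{dm}.
#' @param grid_points number of interpolation grid points (default 101).
#' @return list with \code{mean_roc} / \code{mean_pr} (data frames on the
#'   grid), \code{mean_auc} / \code{mean_aupr} (means of the per-target
#'   areas), \code{curve_auc} (area under the averaged ROC curve) and
#'   \code{per_target} (data frame of per-target auc/aupr).
#' @export
single_target_recovery <- function(dm, approved, grid_points = 101L) {
  stopifnot(inherits(dm, "dsd_matrix"))
  approved <- unique(as.character(approved))
  if (length(approved) < 2L) stop("need at least 2 approved targets")
  bad <- setdiff(approved, dm$node_order)
  if (length(bad) > 0L) stop(sprintf("approved target not in DSD matrix: %s", bad[1L]))
  grid <- seq(0, 1, length.out = grid_points)
  roc_mat <- matrix(NA_real_, length(approved), grid_points)
  pr_mat <- matrix(NA_real_, length(approved), grid_points)
  aucs <- numeric(length(approved))
  auprs <- numeric(length(approved))
  for (i in seq_along(approved)) {
    t <- approved[i]
    others <- setdiff(dm$node_order, t)
    scores <- -dm$d[t, others]  # ascending DSD = descending score
    r <- labeled_ranking(scores, setdiff(approved, t), higher_is_better = TRUE)
    roc <- roc_auc(r)
    pr <- pr_metrics(r, k_values = length(others))
    aucs[i] <- roc$auc
    auprs[i] <- pr$aupr
    roc_mat[i, ] <- approx(roc$curve$fpr, roc$curve$tpr, xout = grid,
                           ties = max, rule = 2)$y
    # step-interpolated precision at each recall grid point: precision of
    # the first sweep point whose recall reaches the grid value
    rec <- pr$curve$recall
    prec <- pr$curve$precision
    pr_mat[i, ] <- vapply(grid, function(rg) {
      j <- which(rec >= rg - 1e-12)
      if (length(j) == 0L) prec[length(prec)] else prec[j[1L]]
    }, 0)
  }
  mean_roc <- data.frame(fpr = grid, tpr = colMeans(roc_mat))
  mean_pr <- data.frame(recall = grid, precision = colMeans(pr_mat))
  curve_auc <- sum(diff(grid) * (head(mean_roc$tpr, -1L) + mean_roc$tpr[-1L]) / 2)
  list(mean_roc = mean_roc, mean_pr = mean_pr,
       mean_auc = mean(aucs), mean_aupr = mean(auprs),
       curve_auc = curve_auc,
       per_target = data.frame(target = approved, auc = aucs, aupr = auprs,
                               stringsAsFactors = FALSE))
}

#' Median combined rank per development stage
#'
#' Compares how a score table ranks targets at different drug-development
#' stages (e.g. launched vs clinical vs preclinical).  Nodes in
#' \code{stage_map} missing from the table are skipped with a warning.
#'
#' @param table \code{score_table} data frame from
#'   \code{\link{prioritize}}.
#' @param stage_map named character vector: node name -> stage label.
#' @return data frame with \code{stage}, \code{n},
#'   \code{median_combined_rank}, ordered by median rank.
#' @export
stage_rank_comparison <- function(table, stage_map) {
  if (length(stage_map) == 0L) stop("stage_map must be nonempty")
  known <- names(stage_map) %in% table$node
  if (any(!known)) {
    warning(sprintf("%d staged node(s) not in the score table; skipped",
                    sum(!known)))
    stage_map <- stage_map[known]
  }
  if (length(stage_map) == 0L) stop("no staged node is present in the score table")
  ranks <- setNames(table$combined_rank, table$node)[names(stage_map)]
  agg <- split(ranks, unname(stage_map))
  empty <- vapply(agg, length, 1L) == 0L
  if (any(empty)) warning("empty stage group(s) omitted")
  agg <- agg[!empty]
  out <- data.frame(stage = names(agg),
                    n = vapply(agg, length, 1L),
                    median_combined_rank = vapply(agg, median, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$median_combined_rank), ]
}

#' Write an evaluation report as JSON
#'
#' @param report list of evaluation results (numeric scalars or vectors).
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
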