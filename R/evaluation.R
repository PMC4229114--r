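#' Evaluate a predicted network against a gold standard
#'
#' Every unordered off-diagonal gene pair is an instance; its label is
#' membership in the gold-standard edge set and its score is the predicted
#' absolute edge weight. Thresholds sweep the distinct scores, with tied
#' scores entering together, which makes the trapezoidal area under the ROC
#' curve identical to the midrank Mann-Whitney statistic. The area under
#' the precision-recall curve uses the step-wise integral
#' `sum_k (R_k - R_{k-1}) P_k`.
#'
#' @param pred a [weighted_network()] prediction.
#' @param truth a [true_network()] over the same gene set.
#' @return an object of class `network_evaluation`: list with `roc_points`
#'   (FPR, TPR), `pr_points` (recall, precision), `auc`, `aupr`,
#'   `n_true_edges`, `n_pairs`.
#' @export
evaluate_network <- function(pred, truth) {
  if (!setequal(rownames(pred), truth$gene_ids)) {
    stop_netaggr("prediction and truth are over different gene sets")
  }
  pred <- as.matrix(pred)[truth$gene_ids, truth$gene_ids]
  adj <- truth_adjacency(truth)
  lt <- lower.tri(pred)
  scores <- abs(pred[lt])
  labels <- adj[lt]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_netaggr("gold standard must contain at least one edge and one non-edge")
  }

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores so they enter the curves together
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  roc_points <- cbind(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc_points[, "fpr"]) *
               (utils::head(roc_points[, "tpr"], -1) +
                  utils::tail(roc_points[, "tpr"], -1)) / 2)

  recall <- tpr
  precision <- tp / (tp + fp)
  pr_points <- cbind(recall = recall, precision = precision)
  aupr <- sum(diff(c(0, recall)) * precision)

  structure(list(roc_points = roc_points, pr_points = pr_points,
                 auc = auc, aupr = aupr,
                 n_true_edges = n_pos, n_pairs = n_pos + n_neg),
            class = "network_evaluation")
}

#' @export
print.network_evaluation <- function(x, ...) {
  cat("<network_evaluation> AUC = ", format(round(x$auc, 4)),
      ", AUPR = ", format(round(x$aupr, 4)),
      " (", x$n_true_edges, " true edges / ", x$n_pairs, " pairs)\n",
      sep = "")
  invisible(x)
}
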