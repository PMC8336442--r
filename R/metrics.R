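#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average-rank tie handling: the
#' probability that a randomly chosen positive outscores a randomly
#' chosen negative, counting ties as 1/2.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 vector of the same length
#' @return AUC in \[0, 1\]
#' @export
auc_score <- function(scores, labels) {
  check_two_classes(labels, "AUC")
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area (average precision): thresholds sweep the unique
#' score values from high to low and each recall increment contributes the
#' precision at that threshold. Tied scores enter as one block.
#'
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\]
#' @export
aupr_score <- function(scores, labels) {
  check_two_classes(labels, "AUPR")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last_of_block <- c(s[-1] != s[-length(s)], TRUE)  # end of each tied block
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels)
  sum(diff(c(0, recall)) * precision)
}

#' F1 score at a fixed threshold
#'
#' @inheritParams auc_score
#' @param threshold classification threshold on the score (default 0.5)
#' @return F1 in \[0, 1\] (0 when there are no true positives)
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

check_two_classes <- function(labels, metric) {
  if (length(labels) == 0L || anyNA(labels))
    abort_metric(sprintf("%s undefined: empty or missing labels", metric))
  if (length(unique(labels)) < 2L)
    abort_metric(sprintf("%s undefined: only one class present", metric))
  invisible(TRUE)
}
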