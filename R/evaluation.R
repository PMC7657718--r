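#' Area under the ROC curve
#'
#' AUC computed as the Mann-Whitney pair statistic — the probability
#' that a random positive outranks a random negative, with half credit
#' for ties — together with the ROC step-curve points from (0,0) to
#' (1,1).
#'
#' @param scores Numeric scores; larger means more positive-like
#'   (dropout is the positive class).
#' @param labels 0/1 labels of the same length.
#' @return A list with `auc` and `roc` (data.table `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC requires both classes to be present")
  }
  r <- rank(scores)  # average ranks give ties half credit
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  roc <- data.table::data.table(threshold = c(Inf, thr),
                                fpr = c(0, fp / n_neg),
                                tpr = c(0, tp / n_pos))
  list(auc = auc, roc = roc)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: the PR step curve is evaluated at
#' each distinct score threshold and the area is the sum of precision
#' times the recall increment. The chance baseline of an uninformative
#' scorer equals the positive-class prevalence.
#'
#' @inheritParams roc_auc
#' @return A list with `pr_auc`, `baseline` (prevalence) and `points`
#'   (data.table `threshold`, `recall`, `precision`).
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("PRAUC requires at least one positive")
  n <- length(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  pp <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  precision <- tp / pp
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(pr_auc = ap, baseline = n_pos / n,
       points = data.table::data.table(threshold = thr, recall = recall,
                                       precision = precision))
}
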