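# Binary classification metrics over triple scores. AUROC comes from pROC;
# average precision is the running-precision-at-positives form; ACC and F1
# are taken at a probability threshold of 0.5.

#' Classification metrics for scored triples
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities in (0, 1).
#' @return A one-row tibble with `ACC`, `AUROC`, `AP`, `F1`.
#' @export
classification_metrics <- function(labels, probabilities) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("metrics need both classes present", call. = FALSE)
  }
  pred <- as.integer(probabilities >= 0.5)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  auroc <- as.numeric(pROC::auc(labels, probabilities, quiet = TRUE,
                                direction = "<", levels = c(0, 1)))
  tibble::tibble(ACC = acc, AUROC = auroc, AP = average_precision(labels, probabilities),
                 F1 = f1)
}

#' Average precision of a ranking
#'
#' Precision averaged at the rank of every positive, with scores sorted in
#' decreasing order (ties broken by original position).
#'
#' @param labels 0/1 vector.
#' @param scores Ranking scores (larger = more positive).
#' @return Scalar in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[ord]
  cum_tp <- cumsum(y)
  prec <- cum_tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}
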