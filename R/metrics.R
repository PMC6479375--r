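#' Confusion matrix of integer-coded predictions
#'
#' @param y_true,y_pred Integer labels in `0:(K-1)`, equal length.
#' @param K Number of classes.
#' @return K x K integer matrix; rows index the true class, columns the
#'   predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= K))
    stop("labels must lie in 0:(K-1)")
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

metrics_from_confusion <- function(cm) {
  n <- sum(cm)
  if (n == 0L) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  tp <- diag(cm)
  pred_tot <- colSums(cm)
  true_tot <- rowSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  # chance agreement from the marginal products
  pe <- sum(true_tot * pred_tot) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps * 4) {
    if (po >= 1) 1 else 0
  } else (po - pe) / (1 - pe)
  list(accuracy = po,
       precision = mean(precision),
       recall = mean(recall),
       f1 = mean(f1),
       kappa = kappa,
       expected_agreement = pe,
       per_class = data.frame(class = seq_len(nrow(cm)) - 1L,
                              precision = precision, recall = recall,
                              f1 = f1, support = true_tot),
       confusion = cm)
}

#' Multi-class classification metrics
#'
#' Accuracy, macro-averaged precision/recall/F1 and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)`, with the chance agreement `p_e` computed from
#' the products of the row and column marginals. Per-class scores with a
#' zero denominator are defined as 0 before macro-averaging.
#'
#' @param y_true,y_pred Integer labels in `0:(K-1)`, equal length.
#' @param K Number of classes.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `kappa`,
#'   `expected_agreement`, `per_class` (data frame) and `confusion`.
#' @examples
#' m <- compute_metrics(c(0, 1, 2, 0), c(0, 1, 2, 1), 3)
#' m$accuracy
#' @export
compute_metrics <- function(y_true, y_pred, K) {
  metrics_from_confusion(confusion_matrix(y_true, y_pred, K))
}
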