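# Regression-deviation and multi-class classification metrics.

#' Regression deviation metrics
#'
#' MAE = mean |e|, RMSE = sqrt(mean e^2), MAPE = mean |e / truth| reported
#' as a fraction (0.32, not 32%).  MAPE requires all truths nonzero and is
#' `NA` when not requested against such data.
#'
#' @param truth,pred Equal-length nonempty numeric vectors.
#' @param mape Compute MAPE (default TRUE); errors on zero truths.
#' @return A list with `mae`, `mape`, `rmse`.
#' @export
regression_metrics <- function(truth, pred, mape = TRUE) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  e <- pred - truth
  out <- list(mae = mean(abs(e)), mape = NA_real_, rmse = sqrt(mean(e^2)))
  if (mape) {
    if (any(truth == 0)) {
      stop("undefined MAPE: truth contains zeros", call. = FALSE)
    }
    out$mape <- mean(abs(e / truth))
  }
  out
}

#' Confusion matrix over health levels
#'
#' @param truth,pred Vectors of labels (coerced to character).
#' @param labels Ordered label set (default the five health levels present
#'   in the data, in [HEALTH_LEVELS] order when applicable).
#' @return A square integer matrix, rows = truth, cols = predicted, of class
#'   `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, labels = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  if (is.null(labels)) {
    seen <- unique(c(truth, pred))
    labels <- if (all(seen %in% HEALTH_LEVELS)) {
      HEALTH_LEVELS[HEALTH_LEVELS %in% seen]
    } else sort(seen)
  }
  m <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("truth", "pred")
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Micro/macro classification metrics from a confusion matrix
#'
#' Micro metrics pool true/false positives over labels; for single-label
#' multi-class data micro-precision = micro-recall = micro-F1 = accuracy
#' (an algebraic identity).  Macro metrics are unweighted means of
#' per-label values; a label never predicted contributes precision 0 with a
#' warning (and analogously for recall on absent labels).
#'
#' @param cm A [confusion_matrix()] (any square numeric matrix with matching
#'   dimnames works).
#' @return A list with `accuracy` and `precision`, `recall`, `f1`, each a
#'   named vector `c(micro, macro)`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) >= 1)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  accuracy <- sum(tp) / total

  micro_p <- sum(tp) / (sum(tp) + sum(fp))
  micro_r <- sum(tp) / (sum(tp) + sum(fn))
  micro_f1 <- if (micro_p + micro_r > 0) 2 * micro_p * micro_r / (micro_p + micro_r) else 0

  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("label(s) ", paste(rownames(cm)[bad], collapse = ", "),
              " have no ", what, "; contributing 0 to the macro mean",
              call. = FALSE)
    }
    ifelse(bad, 0, num / den)
  }
  p_l <- safe_div(tp, tp + fp, "predicted positives")
  r_l <- safe_div(tp, tp + fn, "true instances")
  f1_l <- ifelse(p_l + r_l > 0, 2 * p_l * r_l / (p_l + r_l), 0)

  list(accuracy = accuracy,
       precision = c(micro = micro_p, macro = mean(p_l)),
       recall = c(micro = micro_r, macro = mean(r_l)),
       f1 = c(micro = micro_f1, macro = mean(f1_l)))
}
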