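#' Regression evaluation metrics
#'
#' Coefficient of determination
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, root mean square
#' error, and mean absolute error.
#'
#' @param y Measured values.
#' @param yhat Predicted values.
#' @return One-row tibble `r2`, `rmse`, `mae`, `n`. `r2` is `NA` (with a
#'   warning) when `y` has zero variance.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in the measured values: R^2 is undefined", call. = FALSE)
    NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  tibble::tibble(
    r2 = r2,
    rmse = sqrt(ss_res / length(y)),
    mae = mean(abs(y - yhat)),
    n = length(y)
  )
}

#' Confusion matrix for strain classification
#'
#' Rows are true classes, columns predicted classes, both over
#' [ys_strains()]. Per class, TP is the diagonal entry, FP the column sum
#' minus TP, and FN the row sum minus TP.
#'
#' @param y_true,y_pred Vectors of strain codes (or factors).
#' @return Integer matrix of class `ys_confusion`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  lv <- ys_strains()
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), lv)
  if (length(bad) > 0) {
    stop("label(s) outside the strain classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(y_true, lv), factor(y_pred, lv))
  structure(unclass(cm), dimnames = list(true = lv, predicted = lv),
            class = c("ys_confusion", "matrix"))
}

#' Row-normalized percentage view of a confusion matrix
#' @param cm From [confusion_matrix()].
#' @return Numeric matrix, each row in percent of its true-class count.
#' @export
confusion_percent <- function(cm) {
  sweep(unclass(cm), 1, pmax(rowSums(cm), 1), "/") * 100
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' `Precision = TP / (TP + FP)`, `Recall = TP / (TP + FN)`,
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`, all in percent;
#' overall accuracy is the percentage of correct predictions (trace over
#' total). A class never predicted (or absent from the truth) reports the
#' affected metric as `NA`.
#'
#' @param cm From [confusion_matrix()].
#' @return List with `per_class` (tibble: strain, precision, recall, f1, in
#'   %) and `accuracy` (%).
#' @export
classification_metrics <- function(cm) {
  m <- unclass(cm)
  if (sum(m) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  precision <- unname(ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_))
  recall <- unname(ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_))
  f1 <- f1_score(precision, recall)
  list(
    per_class = tibble::tibble(
      strain = rownames(m),
      precision = precision, recall = recall, f1 = f1
    ),
    accuracy = 100 * sum(tp) / sum(m)
  )
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * p * r / (p + r)`, on whatever scale (percent or
#' fraction) the inputs share.
#'
#' @param precision,recall Numeric vectors.
#' @return Numeric vector; `NA` where either input is `NA`, 0 where both are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall)))
}
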