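#' Confusion matrix with a fixed class order
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class order; defaults to the union of levels, sorted.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(y_true), as.character(y_pred))),
                    method = "radix")
  }
  t_f <- factor(as.character(y_true), levels = classes)
  p_f <- factor(as.character(y_pred), levels = classes)
  unclass(table(true = t_f, predicted = p_f))
}

#' Multiclass Matthews correlation coefficient
#'
#' The K-class generalisation of the MCC: the true and predicted labels are
#' expanded into N x K one-hot indicator matrices X and Y, and the
#' coefficient is `cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y))`, where
#' `cov(A, B)` sums the per-column covariances. Equivalent to Gorodkin's
#' R_K statistic computed from the confusion matrix. Ranges over
#' `[-1, 1]`; 1 is a perfect prediction and values near 0 are chance-like.
#' When either variance term is 0 (e.g. a constant prediction) the result
#' is defined as 0.
#'
#' @param y_true,y_pred equal-length label vectors over the same class set.
#' @return MCC in `[-1, 1]`.
#' @export
multiclass_mcc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  classes <- sort(unique(c(as.character(y_true), as.character(y_pred))),
                  method = "radix")
  n <- length(y_true)
  x <- matrix(0, n, length(classes))
  y <- matrix(0, n, length(classes))
  x[cbind(seq_len(n), match(as.character(y_true), classes))] <- 1
  y[cbind(seq_len(n), match(as.character(y_pred), classes))] <- 1
  cov_sum <- function(a, b) {
    sum(vapply(seq_along(classes), function(k) {
      mean(a[, k] * b[, k]) - mean(a[, k]) * mean(b[, k])
    }, numeric(1)))
  }
  sxy <- cov_sum(x, y)
  sxx <- cov_sum(x, x)
  syy <- cov_sum(y, y)
  if (sxx == 0 || syy == 0) return(0)
  sxy / sqrt(sxx * syy)
}

#' Overall accuracy
#' @param y_true,y_pred equal-length label vectors.
#' @return fraction of exact matches.
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length")
  }
  mean(as.character(y_true) == as.character(y_pred))
}

#' Per-class (individual) accuracy
#'
#' Per-class recall: for each class, the fraction of its true samples that
#' were predicted correctly (diagonal over row sum of the confusion
#' matrix).
#'
#' @param y_true,y_pred equal-length label vectors; every class of
#'   interest must appear in `y_true`.
#' @param classes optional class order.
#' @return named numeric vector, one recall per class present in `y_true`.
#' @export
per_class_accuracy <- function(y_true, y_pred, classes = NULL) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  present <- rowSums(cm) > 0
  acc <- diag(cm) / rowSums(cm)
  acc[present]
}

#' Full metrics report
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return list with `mcc`, `acc`, `per_class` and the confusion matrix.
#' @export
metrics_report <- function(y_true, y_pred) {
  list(
    mcc = multiclass_mcc(y_true, y_pred),
    acc = overall_accuracy(y_true, y_pred),
    per_class = per_class_accuracy(y_true, y_pred),
    confusion = confusion_matrix(y_true, y_pred)
  )
}
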