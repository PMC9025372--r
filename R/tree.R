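#' Fit a single entropy-criterion decision tree
#'
#' Grows an unpruned axis-aligned classification tree by greedy maximisation
#' of information gain (in bits). The tree is the work-horse behind the Monte
#' Carlo feature selection trees, the decision-tree classifier used during
#' incremental feature selection, and the final rule-extraction tree: all
#' three need per-node information gain and sample counts, which this fit
#' exposes directly.
#'
#' Split semantics: a sample goes to the left child when
#' `value <= threshold`. Thresholds are midpoints between consecutive
#' distinct training values. Ties in gain are broken towards the
#' lowest-index feature and smallest threshold; majority-class ties in a
#' leaf are broken towards the first class level. The fit is fully
#' deterministic — no randomness is involved.
#'
#' @param x numeric matrix (samples x features), with column names.
#' @param y factor of class labels, one per row of `x`.
#' @param max_depth maximum tree depth, or `NULL` for unlimited.
#' @param min_split minimum number of samples required to attempt a split.
#' @return An object of class `entropy_tree`: a flat node table (parallel
#'   vectors `feature`, `threshold`, `left`, `right`, `n`, `pred`, `gain`
#'   plus a node x class `counts` matrix), with node 1 the root and
#'   `feature` `NA` at leaves. `gain` is the information gain of each split
#'   in bits.
#' @examples
#' x <- cbind(g1 = c(0, 0, 5, 6))
#' y <- factor(c("a", "a", "b", "b"))
#' tr <- entropy_tree(x, y)
#' predict(tr, x)
#' @export
entropy_tree <- function(x, y, max_depth = NULL, min_split = 2L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nrow(x) != length(y)) {
    stop("`x` has ", nrow(x), " rows but `y` has ", length(y), " labels")
  }
  if (nlevels(y) < 1L) stop("`y` has no classes")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  md <- if (is.null(max_depth)) -1L else as.integer(max_depth)
  fit <- cart_fit_cpp(x, as.integer(y) - 1L, nlevels(y), md,
                      as.integer(min_split))
  structure(
    list(
      feature = ifelse(fit$feature >= 0L, fit$feature + 1L, NA_integer_),
      threshold = fit$threshold,
      left = ifelse(fit$left >= 0L, fit$left + 1L, NA_integer_),
      right = ifelse(fit$right >= 0L, fit$right + 1L, NA_integer_),
      n = fit$n,
      pred = fit$pred + 1L,
      gain = fit$gain,
      counts = fit$counts,
      classes = levels(y),
      feature_names = colnames(x),
      n_train = nrow(x)
    ),
    class = "entropy_tree"
  )
}

#' Predict classes with an entropy tree
#'
#' @param object an [entropy_tree()] fit.
#' @param newdata numeric matrix with at least the columns the tree was
#'   trained on (matched by name when named, by position otherwise).
#' @param ... unused.
#' @return factor of predicted classes, levels as in training.
#' @export
predict.entropy_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop("`newdata` does not provide the tree's ",
         length(object$feature_names), " training features")
  }
  idx <- cart_predict_cpp(
    ifelse(is.na(object$feature), -1L, object$feature - 1L),
    object$threshold,
    ifelse(is.na(object$left), -1L, object$left - 1L),
    ifelse(is.na(object$right), -1L, object$right - 1L),
    object$pred - 1L,
    newdata
  )
  factor(object$classes[idx + 1L], levels = object$classes)
}

#' @export
print.entropy_tree <- function(x, ...) {
  n_leaves <- sum(is.na(x$feature))
  cat("Entropy decision tree:", x$n_train, "training samples,",
      length(x$classes), "classes,", length(x$feature), "nodes (",
      n_leaves, "leaves )\n")
  invisible(x)
}

# Internal: per-feature split-node contributions of a fitted tree, as needed
# by the Monte Carlo feature selection importance score. One row per split
# node: the information gain (bits) and the fraction of the tree's training
# samples reaching that node.
tree_node_contribs <- function(tree) {
  internal <- which(!is.na(tree$feature))
  data.frame(
    feature = tree$feature_names[tree$feature[internal]],
    gain = tree$gain[internal],
    node_fraction = tree$n[internal] / tree$n_train,
    stringsAsFactors = FALSE
  )
}
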