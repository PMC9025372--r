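#' Classifier specification for incremental feature selection
#'
#' Two classifiers are supported: a random forest (`ranger`, predictions
#' by majority vote of the trees, impurity splits) and a single
#' entropy-criterion decision tree ([entropy_tree()], interpretable and
#' the source of the final decision rules).
#'
#' @param kind `"random_forest"` or `"decision_tree"`.
#' @param n_trees trees in the forest (ignored for the decision tree).
#' @param max_depth optional depth cap (decision tree only).
#' @param seed integer seed (forest randomness).
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("random_forest", "decision_tree"),
                            n_trees = 100L, max_depth = NULL, seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Internal: fit/predict behind a uniform contract.
fit_classifier <- function(spec, x, y, seed = spec$seed) {
  if (spec$kind == "random_forest") {
    fit <- ranger::ranger(x = x, y = y, num.trees = spec$n_trees,
                          num.threads = 1L, seed = seed)
    structure(list(spec = spec, fit = fit, features = colnames(x)),
              class = "cellmark_rf")
  } else {
    tree <- entropy_tree(x, y, max_depth = spec$max_depth)
    structure(list(spec = spec, fit = tree, features = colnames(x)),
              class = "cellmark_dt")
  }
}

predict_classifier <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  if (inherits(model, "cellmark_rf")) {
    predict(model$fit, data = x, num.threads = 1L)$predictions
  } else {
    predict(model$fit, x)
  }
}

#' Incremental feature selection configuration
#'
#' @param step subset-size increment: prefixes of the ranked list of sizes
#'   `step, 2*step, ...` are evaluated.
#' @param max_features cap on the largest prefix evaluated.
#' @param n_folds cross-validation folds.
#' @param delta efficiency tolerance on the MCC: the *efficient* feature
#'   count is the smallest prefix whose MCC is within `delta` of the
#'   maximum.
#' @param classifier a [classifier_spec()].
#' @param smote a [smote_config()]; class balancing applied to training
#'   folds.
#' @param smote_in_fold apply SMOTE inside each training fold (default;
#'   held-out folds stay untouched). `FALSE` reproduces the leaky variant
#'   that balances the whole dataset before splitting — provided for
#'   comparison only; evaluation is still restricted to original samples.
#' @param apply_smote disable balancing entirely with `FALSE`.
#' @param seed integer seed driving fold assignment and per-fold RNG.
#' @return an `ifs_config` list.
#' @export
ifs_config <- function(step = 5L, max_features = 1000L, n_folds = 10L,
                       delta = 0.02, classifier = classifier_spec(),
                       smote = smote_config(), smote_in_fold = TRUE,
                       apply_smote = TRUE, seed = 0L) {
  if (step < 1) stop("step must be >= 1")
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (delta < 0) stop("delta must be >= 0")
  structure(list(step = as.integer(step),
                 max_features = as.integer(max_features),
                 n_folds = as.integer(n_folds), delta = delta,
                 classifier = classifier, smote = smote,
                 smote_in_fold = isTRUE(smote_in_fold),
                 apply_smote = isTRUE(apply_smote),
                 seed = as.integer(seed)),
            class = "ifs_config")
}

#' Prefix sizes swept by incremental feature selection
#'
#' @param n_ranked length of the ranked feature list.
#' @param step size increment.
#' @param max_features cap on the largest prefix.
#' @return increasing integer vector `step, 2*step, ...` up to
#'   `min(n_ranked, max_features)`; when the bound is not a multiple of
#'   `step` it is appended as a final partial prefix.
#' @export
build_subsets <- function(n_ranked, step = 5L, max_features = 1000L) {
  if (n_ranked < 1) stop("ranked feature list is empty")
  bound <- min(n_ranked, max_features)
  sizes <- if (bound < step) integer(0) else seq.int(step, bound, by = step)
  if (length(sizes) == 0 || sizes[length(sizes)] != bound) {
    sizes <- c(sizes, bound)
  }
  as.integer(sizes)
}

#' Cross-validated evaluation of one feature prefix
#'
#' Stratified `n_folds`-fold cross-validation: in each fold the training
#' part (restricted to the prefix features) is SMOTE-balanced, the
#' classifier is fit on it, and the untouched held-out fold is predicted.
#' Out-of-fold predictions are pooled over all folds and scored once —
#' only original (never synthetic) samples are ever evaluated.
#'
#' @param matrix expression matrix.
#' @param labels class factor aligned to rows.
#' @param features character vector: the feature prefix.
#' @param config an [ifs_config()].
#' @return list with `mcc`, `acc`, `per_class` (named per-class recall)
#'   and the pooled `predictions` factor.
#' @export
evaluate_subset <- function(matrix, labels, features, config = ifs_config()) {
  missing <- setdiff(features, colnames(matrix))
  if (length(missing) > 0) {
    stop("features absent from matrix: ", paste(head(missing, 5),
                                                collapse = ", "))
  }
  labels <- as.factor(labels)
  x_all <- matrix[, features, drop = FALSE]
  n <- nrow(x_all)
  k_tag <- paste0("ifs_k", length(features))

  if (config$apply_smote && !config$smote_in_fold) {
    # leaky variant: balance once, before splitting
    bal <- smote_balance(x_all, labels,
                         smote_config(config$smote$k_neighbors,
                                      stream_seed(config$seed, k_tag)))
    x_cv <- bal$matrix
    y_cv <- bal$labels
    original <- !bal$is_synthetic
  } else {
    x_cv <- x_all
    y_cv <- labels
    original <- rep(TRUE, n)
  }

  preds <- factor(rep(NA_character_, nrow(x_cv)), levels = levels(labels))
  with_stream(config$seed, k_tag, {
    fold <- stratified_folds(y_cv, config$n_folds)
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      if (!any(!tr)) next
      x_tr <- x_cv[tr, , drop = FALSE]
      y_tr <- y_cv[tr]
      if (config$apply_smote && config$smote_in_fold) {
        bal <- smote_balance(
          x_tr, y_tr,
          smote_config(config$smote$k_neighbors,
                       stream_seed(config$seed,
                                   paste0(k_tag, "_fold", f))))
        x_tr <- bal$matrix
        y_tr <- bal$labels
      }
      model <- fit_classifier(config$classifier, x_tr, y_tr,
                              seed = stream_seed(config$seed,
                                                 paste0(k_tag, "_fit", f)))
      preds[!tr] <- predict_classifier(model, x_cv[!tr, , drop = FALSE])
    }
  })
  y_eval <- y_cv[original & !is.na(preds)]
  p_eval <- preds[original & !is.na(preds)]
  list(mcc = multiclass_mcc(y_eval, p_eval),
       acc = overall_accuracy(y_eval, p_eval),
       per_class = per_class_accuracy(y_eval, p_eval,
                                      classes = levels(labels)),
       predictions = preds[seq_len(n)])
}

#' Incremental feature selection over a ranked feature list
#'
#' Sweeps nested top-k prefixes of the ranked list, evaluates each with
#' SMOTE-balanced stratified cross-validation ([evaluate_subset()]), and
#' selects two feature counts: `optimal_k`, the smallest prefix achieving
#' the maximum MCC, and `efficient_k`, the smallest prefix whose MCC is
#' within `delta` of that maximum (a near-optimal classifier that needs
#' far fewer genes).
#'
#' @param matrix expression matrix.
#' @param labels class factor aligned to rows.
#' @param ranked ranked feature data.frame (`gene`, `ri`), e.g. from
#'   [run_mcfs()].
#' @param config an [ifs_config()].
#' @return an `ifs_curve` object: list with `records` (one row per prefix
#'   size: `n_features`, `mcc`, `acc`, one column per class),
#'   `optimal_k` and `efficient_k`.
#' @export
run_ifs <- function(matrix, labels, ranked, config = ifs_config()) {
  sizes <- build_subsets(nrow(ranked), config$step, config$max_features)
  labels <- as.factor(labels)
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    res <- evaluate_subset(matrix, labels,
                           ranked$gene[seq_len(sizes[i])], config)
    row <- data.frame(n_features = sizes[i], mcc = res$mcc, acc = res$acc,
                      check.names = FALSE)
    for (cl in levels(labels)) row[[cl]] <- unname(res$per_class[cl])
    rows[[i]] <- row
  }
  records <- do.call(rbind, rows)
  sel <- select_k(records$n_features, records$mcc, config$delta)
  structure(list(records = records, optimal_k = sel$optimal_k,
                 efficient_k = sel$efficient_k),
            class = "ifs_curve")
}

# Internal: optimal and efficient feature counts from an MCC curve.
# optimal_k = smallest size achieving the maximum MCC; efficient_k =
# smallest size whose MCC is within delta of that maximum.
select_k <- function(sizes, mccs, delta) {
  best <- max(mccs)
  list(optimal_k = as.integer(sizes[which(mccs == best)[1]]),
       efficient_k = as.integer(sizes[which(mccs >= best - delta)[1]]))
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("IFS curve over", nrow(x$records), "feature-subset sizes\n")
  cat("  max MCC:", sprintf("%.4f", max(x$records$mcc)),
      "at optimal_k =", x$optimal_k, "\n")
  cat("  efficient_k =", x$efficient_k, "( MCC",
      sprintf("%.4f", x$records$mcc[x$records$n_features ==
                                      x$efficient_k]), ")\n")
  invisible(x)
}
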