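#' Monte Carlo feature selection configuration
#'
#' Defaults follow the usual MCFS regime: each projection holds about 5%
#' of the features (`m = ceiling(0.05 * d)`, at least 1) and the number of
#' projections is scaled so each feature is expected in roughly 300
#' projections (`s = ceiling(300 * d / m)`, capped at 20000), which gives
#' stable importance estimates at desk scale.
#'
#' @param d total number of candidate features.
#' @param m projection size (features per random subset).
#' @param s number of projections.
#' @param t train/test resplits (trees) per projection.
#' @param u exponent on the tree's weighted accuracy in the importance
#'   score.
#' @param v exponent on the node sample fraction.
#' @param train_fraction fraction of samples in each tree's training
#'   split.
#' @param seed integer seed.
#' @return an `mcfs_config` list.
#' @export
mcfs_config <- function(d, m = NULL, s = NULL, t = 5L, u = 1, v = 1,
                        train_fraction = 0.66, seed = 0L) {
  d <- as.integer(d)
  if (is.null(m)) m <- max(1L, as.integer(ceiling(0.05 * d)))
  if (is.null(s)) s <- min(20000L, as.integer(ceiling(300 * d / m)))
  m <- as.integer(m); s <- as.integer(s); t <- as.integer(t)
  if (m < 1 || m > d) stop("projection size m must be in [1, d]")
  if (s < 1 || t < 1) stop("s and t must be >= 1")
  if (u < 0 || v < 0) stop("u and v must be >= 0")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  structure(list(d = d, m = m, s = s, t = t, u = u, v = v,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "mcfs_config")
}

#' Draw a random feature projection
#'
#' @param d total features.
#' @param m projection size.
#' @return sorted integer vector: a uniformly drawn m-subset of `1:d`
#'   without replacement (uses the current RNG state).
#' @export
draw_projection <- function(d, m) {
  if (m < 1 || m > d) stop("m must be in [1, d]")
  sort(sample.int(d, m))
}

#' Evaluate one decision tree on a feature projection
#'
#' Stratified random train/test split, a single entropy-criterion tree fit
#' on the training part, and evaluation on the held-out part. Returns the
#' tree's weighted accuracy (unweighted mean of per-class recall on the
#' classes present in the test split) and, for every split node, the
#' information gain (bits) and the fraction of training samples reaching
#' the node — the raw material of the relative-importance score.
#'
#' @param x numeric matrix restricted to the projected features.
#' @param y class factor.
#' @param train_fraction training fraction of the stratified split.
#' @return a `tree_record`: list with `wacc` and `contribs` (data.frame
#'   `feature`, `gain`, `node_fraction`), or `NULL` when no valid split
#'   could be drawn (degenerate labels; logged as a warning).
#' @export
evaluate_tree <- function(x, y, train_fraction = 0.66) {
  y <- as.factor(y)
  for (attempt in seq_len(10L)) {
    train <- stratified_split(y, train_fraction)
    if (nlevels(droplevels(y[train])) >= 2 && any(!train)) break
    if (attempt == 10L) {
      warning("could not draw a train split with >= 2 classes; ",
              "projection skipped")
      return(NULL)
    }
  }
  tree <- entropy_tree(x[train, , drop = FALSE], y[train])
  pred <- predict(tree, x[!train, , drop = FALSE])
  y_test <- droplevels(y[!train])
  recalls <- vapply(levels(y_test), function(cl) {
    mean(as.character(pred[y_test == cl]) == cl)
  }, numeric(1))
  list(wacc = mean(recalls), contribs = tree_node_contribs(tree))
}

#' Aggregate tree records into relative-importance scores
#'
#' The relative importance of feature `f` sums, over every tree and every
#' node where `f` splits, the product
#' `wacc^u * gain * node_fraction^v`: trees that generalise poorly and
#' nodes deep in the tree (touching few samples) contribute less. Features
#' never selected get importance 0.
#'
#' @param records list of tree records (see [evaluate_tree()]).
#' @param u,v exponents on the weighted accuracy and node fraction.
#' @param feature_names full feature universe (so unseen features appear
#'   with importance 0).
#' @return data.frame (`gene`, `ri`) sorted by decreasing `ri`; ties keep
#'   the original feature order.
#' @export
relative_importance <- function(records, u = 1, v = 1,
                                feature_names = NULL) {
  records <- Filter(Negate(is.null), records)
  if (length(records) == 0) stop("no tree records to aggregate")
  if (is.null(feature_names)) {
    feature_names <- unique(unlist(lapply(records, function(r) {
      r$contribs$feature
    })))
  }
  ri <- setNames(numeric(length(feature_names)), feature_names)
  for (rec in records) {
    cb <- rec$contribs
    if (nrow(cb) == 0) next
    contrib <- (rec$wacc^u) * cb$gain * (cb$node_fraction^v)
    agg <- tapply(contrib, cb$feature, sum)
    ri[names(agg)] <- ri[names(agg)] + agg
  }
  ord <- order(-ri, seq_along(ri))
  data.frame(gene = feature_names[ord], ri = unname(ri[ord]),
             stringsAsFactors = FALSE)
}

#' Monte Carlo feature selection ranking
#'
#' Draws `s` random projections of `m` features, grows `t` entropy trees
#' per projection (each on a fresh stratified train/test split), and
#' aggregates every split node's information gain — weighted by the tree's
#' held-out accuracy and the node's sample fraction — into a ranked
#' feature list.
#'
#' @param matrix expression matrix restricted to the candidate genes.
#' @param labels class factor aligned to rows.
#' @param config an [mcfs_config()]; defaults are derived from
#'   `ncol(matrix)`.
#' @param keep_records keep the raw per-tree records as the `"records"`
#'   attribute (memory-heavy; intended for small validation runs).
#' @return ranked data.frame (`gene`, `ri`), decreasing `ri`.
#' @export
run_mcfs <- function(matrix, labels, config = NULL, keep_records = FALSE) {
  labels <- as.factor(labels)
  if (nrow(matrix) != length(labels)) {
    stop("matrix and labels are not aligned")
  }
  if (is.null(config)) config <- mcfs_config(d = ncol(matrix))
  if (config$d != ncol(matrix)) {
    stop("config built for d = ", config$d, " features but matrix has ",
         ncol(matrix))
  }
  genes <- colnames(matrix)
  ri <- setNames(numeric(length(genes)), genes)
  records <- if (keep_records) vector("list", config$s * config$t) else NULL
  with_stream(config$seed, "mcfs", {
    for (proj in seq_len(config$s)) {
      idx <- draw_projection(config$d, config$m)
      sub <- matrix[, idx, drop = FALSE]
      for (rep in seq_len(config$t)) {
        rec <- evaluate_tree(sub, labels, config$train_fraction)
        if (keep_records) {
          records[[(proj - 1L) * config$t + rep]] <- rec
        }
        if (is.null(rec) || nrow(rec$contribs) == 0) next
        contrib <- (rec$wacc^config$u) * rec$contribs$gain *
          (rec$contribs$node_fraction^config$v)
        agg <- tapply(contrib, rec$contribs$feature, sum)
        ri[names(agg)] <- ri[names(agg)] + agg
      }
    }
  })
  ord <- order(-ri, seq_along(ri))
  out <- data.frame(gene = genes[ord], ri = unname(ri[ord]),
                    stringsAsFactors = FALSE)
  if (keep_records) attr(out, "records") <- records
  out
}
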