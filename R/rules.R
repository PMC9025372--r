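#' Fit the final decision tree for rule extraction
#'
#' Trains one entropy-criterion tree on the full dataset restricted to the
#' selected feature prefix, optionally SMOTE-balancing the classes first
#' (default) so minority cell types are not drowned out of the leaves.
#'
#' @param matrix expression matrix.
#' @param labels class factor aligned to rows.
#' @param features character vector: the decision-tree-optimal feature
#'   prefix from [run_ifs()].
#' @param balance SMOTE-balance the training data before fitting.
#' @param smote a [smote_config()] used when `balance = TRUE`.
#' @param max_depth optional depth cap.
#' @param seed integer seed (drives the SMOTE draws).
#' @return an [entropy_tree()] fit on the (possibly balanced) data.
#' @export
fit_final_tree <- function(matrix, labels, features, balance = TRUE,
                           smote = smote_config(), max_depth = NULL,
                           seed = 0L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("need at least 2 classes to fit the final tree")
  }
  x <- matrix[, features, drop = FALSE]
  y <- labels
  if (balance) {
    bal <- smote_balance(x, y, smote_config(smote$k_neighbors,
                                            stream_seed(seed, "final_tree")))
    x <- bal$matrix
    y <- bal$labels
  }
  entropy_tree(x, y, max_depth = max_depth)
}

# Internal: leaf node id reached by each row of x.
tree_leaf_ids <- function(tree, x) {
  x <- as.matrix(x)[, tree$feature_names, drop = FALSE]
  vapply(seq_len(nrow(x)), function(i) {
    node <- 1L
    while (!is.na(tree$feature[node])) {
      node <- if (x[i, tree$feature[node]] <= tree$threshold[node]) {
        tree$left[node]
      } else {
        tree$right[node]
      }
    }
    node
  }, integer(1))
}

#' Extract IF-THEN classification rules from a decision tree
#'
#' One rule per leaf: the conjunction of the edge conditions on the
#' root-to-leaf path (`gene <= threshold` for left edges, `gene >
#' threshold` for right edges) predicting the leaf's majority class. The
#' rules of one tree are mutually exclusive and exhaustive. Support
#' (samples satisfying all conditions) and confidence (fraction of those
#' with the predicted class) are computed on the supplied original
#' samples — not on synthetic balanced copies — so the reported patterns
#' describe real cells. Rules are sorted by decreasing support, ties by
#' decreasing confidence then extraction order, and the list is capped at
#' `top_n`.
#'
#' @param tree an [entropy_tree()].
#' @param matrix original training expression matrix (pre-balancing).
#' @param labels original class factor.
#' @param top_n cap on the number of reported rules.
#' @return a `rule_set`: list with `rules` (each a list `conditions`
#'   data.frame (`gene`, `op`, `threshold`), `class`, `support`,
#'   `confidence`) and `n_extracted`.
#' @export
extract_rules <- function(tree, matrix, labels, top_n = 1000L) {
  labels <- as.factor(labels)
  leaves <- which(is.na(tree$feature))

  # root-to-leaf condition paths by walking down from the root
  paths <- vector("list", length(tree$feature))
  paths[[1]] <- data.frame(gene = character(0), op = character(0),
                           threshold = numeric(0), stringsAsFactors = FALSE)
  for (node in seq_along(tree$feature)) {
    if (is.na(tree$feature[node])) next
    gene <- tree$feature_names[tree$feature[node]]
    thr <- tree$threshold[node]
    paths[[tree$left[node]]] <- rbind(
      paths[[node]],
      data.frame(gene = gene, op = "<=", threshold = thr,
                 stringsAsFactors = FALSE))
    paths[[tree$right[node]]] <- rbind(
      paths[[node]],
      data.frame(gene = gene, op = ">", threshold = thr,
                 stringsAsFactors = FALSE))
  }

  leaf_of <- tree_leaf_ids(tree, matrix)
  rules <- lapply(leaves, function(leaf) {
    in_leaf <- leaf_of == leaf
    cls <- tree$classes[tree$pred[leaf]]
    support <- sum(in_leaf)
    confidence <- if (support > 0) {
      mean(as.character(labels[in_leaf]) == cls)
    } else 0
    list(conditions = paths[[leaf]], class = cls,
         support = as.integer(support), confidence = confidence)
  })
  support <- vapply(rules, `[[`, integer(1), "support")
  confidence <- vapply(rules, `[[`, numeric(1), "confidence")
  ord <- order(-support, -confidence, seq_along(rules))
  rules <- rules[ord][seq_len(min(top_n, length(rules)))]
  structure(list(rules = rules, n_extracted = length(rules)),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("Rule set with", x$n_extracted, "rules\n")
  for (line in head(format_rules(x), 5)) cat(" ", line, "\n")
  if (x$n_extracted > 5) cat("  ...\n")
  invisible(x)
}

#' Classify samples with a rule set
#'
#' Each sample must satisfy exactly one rule (the rules of one tree
#' partition the feature space); its predicted class is that rule's
#' class. Boundary semantics match the tree's splits: a condition
#' `gene <= threshold` matches a value exactly at the threshold.
#'
#' @param rules a `rule_set` from [extract_rules()].
#' @param x numeric matrix (samples x genes) or a single named numeric
#'   vector covering every gene the rules reference.
#' @return character vector of predicted classes.
#' @export
apply_rules <- function(rules, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL,
                                                                names(x)))
  needed <- unique(unlist(lapply(rules$rules, function(r) {
    r$conditions$gene
  })))
  missing <- setdiff(needed, colnames(x))
  if (length(missing) > 0) {
    stop("sample does not cover gene(s): ", paste(head(missing, 5),
                                                  collapse = ", "))
  }
  vapply(seq_len(nrow(x)), function(i) {
    matches <- which(vapply(rules$rules, function(r) {
      cond <- r$conditions
      if (nrow(cond) == 0) return(TRUE)
      vals <- x[i, cond$gene]
      all(ifelse(cond$op == "<=", vals <= cond$threshold,
                 vals > cond$threshold))
    }, logical(1)))
    if (length(matches) == 0) {
      stop("no rule matches sample ", i, " (corrupted or truncated rule set)")
    }
    if (length(matches) > 1) {
      stop("multiple rules match sample ", i,
           " (rules of one tree must be disjoint)")
    }
    rules$rules[[matches]]$class
  }, character(1))
}
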