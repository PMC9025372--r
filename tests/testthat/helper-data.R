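# Shared fixtures, built in code.

# Small separable 2-feature, 3-class dataset.
toy_separable <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  classes <- c("a", "b", "c")
  centers <- list(a = c(0, 0), b = c(10, 0), c = c(0, 10))
  x <- do.call(rbind, lapply(classes, function(cl) {
    sweep(matrix(rnorm(n_per_class * 2, sd = 0.5), ncol = 2), 2,
          centers[[cl]], `+`)
  }))
  colnames(x) <- c("gA", "gB")
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  list(x = x, y = factor(rep(classes, each = n_per_class)))
}

# Independent straight-line recomputation of the relative-importance sum
# from logged tree records (the brute-force oracle for the aggregation).
ri_oracle <- function(records, u, v, feature_names) {
  ri <- setNames(numeric(length(feature_names)), feature_names)
  for (rec in records) {
    if (is.null(rec)) next
    for (i in seq_len(nrow(rec$contribs))) {
      f <- rec$contribs$feature[i]
      ri[f] <- ri[f] +
        rec$wacc^u * rec$contribs$gain[i] * rec$contribs$node_fraction[i]^v
    }
  }
  ri
}

# Gorodkin's R_K computed directly from a confusion matrix: the
# independent oracle for the one-hot covariance MCC.
rk_from_confusion <- function(cm) {
  n <- sum(cm)
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- n * sum(diag(cm)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(t_k^2)) * sqrt(n^2 - sum(p_k^2))
  if (den == 0) 0 else num / den
}

# Classical closed-form binary MCC.
binary_mcc <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}
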