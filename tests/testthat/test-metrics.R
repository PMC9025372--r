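test_that("multiclass MCC behaves at the extremes", {
  y <- c("a", "a", "b", "b", "c", "c")
  expect_equal(multiclass_mcc(y, y), 1.0)
  expect_equal(multiclass_mcc(y, rep("a", 6)), 0)  # constant prediction
  expect_error(multiclass_mcc(y, y[-1]), "length")
})

test_that("multiclass MCC reduces to the classical binary MCC", {
  # the worked 2x2 example
  y_true <- c(rep("pos", 40), rep("neg", 5), rep("pos", 10), rep("neg", 45))
  y_pred <- c(rep("pos", 40), rep("pos", 5), rep("neg", 10), rep("neg", 45))
  expect_equal(multiclass_mcc(y_true, y_pred),
               binary_mcc(tp = 40, fp = 5, fn = 10, tn = 45),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:1000) {
    cm <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(cm) == 0) next
    y_t <- rep(c("A", "A", "B", "B"), as.vector(cm))
    y_p <- rep(c("A", "B", "A", "B"), as.vector(cm))
    if (length(unique(y_t)) < 2 && length(unique(y_p)) < 2) next
    expect_equal(multiclass_mcc(y_t, y_p),
                 binary_mcc(cm[1, 1], cm[2, 1], cm[1, 2], cm[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("multiclass MCC equals Gorodkin's R_K from the confusion matrix", {
  set.seed(22)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    cm <- matrix(sample(0:10, k * k, replace = TRUE), k)
    if (sum(cm) == 0) next
    classes <- LETTERS[1:k]
    y_t <- rep(rep(classes, each = k), as.vector(t(cm)))
    y_p <- rep(rep(classes, times = k), as.vector(t(cm)))
    expect_equal(multiclass_mcc(y_t, y_p), rk_from_confusion(cm),
                 tolerance = 1e-10)
  }
})

test_that("MCC is invariant under a consistent relabelling", {
  set.seed(23)
  y_t <- sample(c("a", "b", "c"), 60, replace = TRUE)
  y_p <- sample(c("a", "b", "c"), 60, replace = TRUE)
  swap <- function(v) ifelse(v == "a", "b", ifelse(v == "b", "a", v))
  expect_equal(multiclass_mcc(y_t, y_p),
               multiclass_mcc(swap(y_t), swap(y_p)), tolerance = 1e-12)
})

test_that("accuracies follow their definitions", {
  y_t <- c("a", "a", "b", "b")
  expect_equal(overall_accuracy(y_t, y_t), 1.0)
  expect_equal(overall_accuracy(y_t, rev(y_t)), 0.0)
  expect_equal(overall_accuracy(y_t, c("a", "a", "b", "a")), 0.75)

  pc <- per_class_accuracy(y_t, c("a", "a", "b", "a"))
  expect_equal(unname(pc), c(1.0, 0.5))
  # class absent from predictions scores 0
  pc2 <- per_class_accuracy(c("a", "b"), c("a", "a"))
  expect_equal(unname(pc2["b"]), 0.0)

  # overall accuracy is the class-size-weighted mean of per-class accuracy
  set.seed(24)
  y_t <- sample(c("a", "b", "c"), 100, replace = TRUE)
  y_p <- sample(c("a", "b", "c"), 100, replace = TRUE)
  pc <- per_class_accuracy(y_t, y_p)
  w <- table(y_t)[names(pc)]
  expect_equal(overall_accuracy(y_t, y_p),
               sum(pc * as.numeric(w)) / sum(w), tolerance = 1e-12)
})

test_that("the confusion matrix counts true-by-predicted pairs", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(true = c("a", "b"),
                                      predicted = c("a", "b"))),
               ignore_attr = "class")
  expect_equal(sum(cm), 3)
})
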