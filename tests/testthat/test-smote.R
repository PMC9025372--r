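test_that("already-balanced input passes through unchanged", {
  x <- matrix(runif(20), 10, 2,
              dimnames = list(paste0("c", 1:10), c("g1", "g2")))
  y <- factor(rep(c("a", "b"), each = 5))
  out <- smote_balance(x, y)
  expect_identical(out$matrix, x)
  expect_identical(out$labels, y)
  expect_false(any(out$is_synthetic))
})

test_that("oversampling equalises every class to the majority count", {
  set.seed(31)
  x <- matrix(runif(60), ncol = 2)
  rownames(x) <- paste0("c", 1:30)
  colnames(x) <- c("g1", "g2")
  y <- factor(rep(c("a", "b", "c"), times = c(4, 10, 16)))
  out <- smote_balance(x, y, smote_config(k_neighbors = 3, seed = 1))
  expect_identical(unname(as.vector(table(out$labels))), rep(16L, 3))
  # originals preserved, in order, first
  expect_identical(out$matrix[1:30, ], x)
  expect_identical(out$is_synthetic, c(rep(FALSE, 30), rep(TRUE, 18)))
})

test_that("synthetic points interpolate their two recorded parents", {
  set.seed(32)
  x <- matrix(rnorm(40 * 3), ncol = 3,
              dimnames = list(NULL, paste0("g", 1:3)))
  y <- factor(rep(c("min", "maj"), times = c(10, 30)))
  out <- smote_balance(x, y, smote_config(seed = 2))
  synth <- which(out$is_synthetic)
  expect_identical(nrow(out$provenance), length(synth))
  for (i in seq_along(synth)) {
    z <- out$matrix[synth[i], ]
    a <- x[out$provenance$base[i], ]
    b <- x[out$provenance$neighbor[i], ]
    expect_true(all(z >= pmin(a, b) - 1e-12 & z <= pmax(a, b) + 1e-12))
    expect_equal(unname(z), unname(a + out$provenance$lambda[i] * (b - a)),
                 tolerance = 1e-12)
    # parents are same-class
    expect_identical(as.character(y[out$provenance$base[i]]), "min")
    expect_identical(as.character(y[out$provenance$neighbor[i]]), "min")
  }
})

test_that("lambda endpoints and 1-D convexity behave as defined", {
  x <- matrix(c(1, 2, 10, 11, 12, 13, 14, 15), ncol = 1,
              dimnames = list(NULL, "g"))
  y <- factor(rep(c("min", "maj"), times = c(2, 6)))
  # lambda forced to 0: synthetic rows duplicate existing minority rows
  out0 <- smote_balance(x, y, smote_config(k_neighbors = 1, seed = 3),
                        lambda = 0)
  expect_true(all(out0$matrix[out0$is_synthetic, 1] %in% c(1, 2)))
  # free lambda: all 4 synthetic values inside the minority segment [1, 2]
  out <- smote_balance(x, y, smote_config(k_neighbors = 1, seed = 3))
  synth_vals <- out$matrix[out$is_synthetic, 1]
  expect_length(synth_vals, 4L)
  expect_true(all(synth_vals >= 1 & synth_vals <= 2))
})

test_that("seeds reproduce and degenerate classes are caught", {
  set.seed(33)
  x <- matrix(runif(30), ncol = 2, dimnames = list(NULL, c("g1", "g2")))
  y <- factor(rep(c("a", "b", "c"), times = c(3, 5, 7)))
  a <- smote_balance(x, y, smote_config(k_neighbors = 2, seed = 7))
  b <- smote_balance(x, y, smote_config(k_neighbors = 2, seed = 7))
  expect_identical(a, b)

  y1 <- factor(rep(c("a", "b"), times = c(1, 14)))
  expect_error(smote_balance(x, y1, smote_config(seed = 1)), "single sample")

  # k larger than class size - 1 is clamped with a warning
  y2 <- factor(rep(c("a", "b"), times = c(5, 10)))
  expect_warning(
    smote_balance(x, y2, smote_config(k_neighbors = 10, seed = 1)),
    "clamped to 4")
})
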