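test_that("a depth-1 tree yields two complementary rules", {
  x <- cbind(g = c(1, 2, 8, 9))
  y <- factor(c("a", "a", "b", "b"))
  tree <- entropy_tree(x, y)
  rules <- extract_rules(tree, x, y)
  expect_identical(rules$n_extracted, 2L)
  expect_equal(sum(vapply(rules$rules, `[[`, integer(1), "support")), 4L)
  ops <- vapply(rules$rules, function(r) r$conditions$op, character(1))
  expect_setequal(ops, c("<=", ">"))
  expect_true(all(vapply(rules$rules, `[[`, numeric(1),
                         "confidence") == 1))
})

test_that("a single-leaf tree gives one unconditional rule", {
  x <- cbind(g = rep(1, 5))
  y <- factor(c("a", "a", "a", "b", "b"))
  tree <- entropy_tree(x, y)  # constant feature: no split
  rules <- extract_rules(tree, x, y)
  expect_identical(rules$n_extracted, 1L)
  expect_identical(nrow(rules$rules[[1]]$conditions), 0L)
  expect_identical(rules$rules[[1]]$support, 5L)
  expect_identical(rules$rules[[1]]$class, "a")
  expect_identical(apply_rules(rules, cbind(g = 3)), "a")
})

test_that("rules reproduce the tree's predictions exactly", {
  sim <- simulate_profiles(synth_config(
    n_classes = 3, class_sizes = c(25, 40, 60), n_genes = 20,
    markers_per_class = 3, seed = 71))
  features <- colnames(sim$matrix)[1:12]
  tree <- fit_final_tree(sim$matrix, sim$labels, features, balance = TRUE,
                         seed = 1)
  rules <- extract_rules(tree, sim$matrix, sim$labels)
  pred_tree <- predict(tree, sim$matrix[, features, drop = FALSE])
  pred_rules <- apply_rules(rules, sim$matrix)
  expect_identical(as.character(pred_tree), pred_rules)
  expect_equal(sum(vapply(rules$rules, `[[`, integer(1), "support")),
               nrow(sim$matrix))
  # sorted by support, ties by confidence
  supports <- vapply(rules$rules, `[[`, integer(1), "support")
  expect_true(all(diff(supports) <= 0))
})

test_that("exactly one rule fires anywhere in feature space", {
  toy <- toy_separable(n_per_class = 15, seed = 72)
  tree <- entropy_tree(toy$x, toy$y)
  rules <- extract_rules(tree, toy$x, toy$y)
  grid <- as.matrix(expand.grid(gA = seq(-2, 12, length.out = 15),
                                gB = seq(-2, 12, length.out = 15)))
  for (i in seq_len(nrow(grid))) {
    fired <- vapply(rules$rules, function(r) {
      cond <- r$conditions
      all(ifelse(cond$op == "<=", grid[i, cond$gene] <= cond$threshold,
                 grid[i, cond$gene] > cond$threshold))
    }, logical(1))
    expect_identical(sum(fired), 1L)
  }
  # boundary convention: gene <= threshold matches a value exactly there
  thr <- rules$rules[[1]]$conditions$threshold[1]
  gene <- rules$rules[[1]]$conditions$gene[1]
  op <- rules$rules[[1]]$conditions$op[1]
  pt <- setNames(c(thr, thr), c("gA", "gB"))
  expect_identical(apply_rules(rules, pt),
                   unname(apply_rules(rules, rbind(pt))))
})

test_that("rule application validates its inputs", {
  x <- cbind(g = c(1, 2, 8, 9))
  y <- factor(c("a", "a", "b", "b"))
  rules <- extract_rules(entropy_tree(x, y), x, y)
  expect_error(apply_rules(rules, cbind(other = 1)), "does not cover")
  # a truncated rule set loses the partition property
  truncated <- structure(list(rules = rules$rules[1], n_extracted = 1L),
                         class = "rule_set")
  covered <- rules$rules[[1]]
  bad_val <- if (covered$conditions$op[1] == "<=") {
    covered$conditions$threshold[1] + 1
  } else {
    covered$conditions$threshold[1] - 1
  }
  expect_error(apply_rules(truncated, cbind(g = bad_val)), "no rule")
})

test_that("an unbalanced fit lets the majority class dominate the leaves", {
  sim <- simulate_profiles(synth_config(
    n_classes = 3, class_sizes = c(15, 20, 200), n_genes = 20,
    markers_per_class = 3, dropout_rate = 0.5, seed = 73))
  features <- colnames(sim$matrix)[1:9]
  tree_raw <- fit_final_tree(sim$matrix, sim$labels, features,
                             balance = FALSE, seed = 2)
  leaves <- which(is.na(tree_raw$feature))
  leaf_classes <- tree_raw$classes[tree_raw$pred[leaves]]
  counts <- table(factor(leaf_classes, levels = tree_raw$classes))
  expect_identical(names(which.max(counts)), "type03")
  expect_error(fit_final_tree(sim$matrix,
                              factor(rep("a", nrow(sim$matrix))),
                              features), "2 classes")
})
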