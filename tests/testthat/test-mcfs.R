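test_that("projections are uniform m-subsets without replacement", {
  set.seed(51)
  expect_identical(draw_projection(4, 4), 1:4)
  expect_error(draw_projection(3, 4), "m must be")
  # m = 1, d = 3: each feature drawn ~uniformly over 3000 draws
  draws <- replicate(3000, draw_projection(3, 1))
  counts <- table(factor(draws, levels = 1:3))
  sigma <- sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 1000) <= 3 * sigma))
  # fixed RNG state reproduces the subset
  set.seed(99); a <- draw_projection(50, 5)
  set.seed(99); b <- draw_projection(50, 5)
  expect_identical(a, b)
})

test_that("tree records capture weighted accuracy and node contributions", {
  set.seed(52)
  # perfectly separable 2-class data on one feature
  x <- cbind(g = c(rep(0, 20), rep(10, 20)))
  y <- factor(rep(c("a", "b"), each = 20))
  rec <- evaluate_tree(x, y, train_fraction = 0.66)
  expect_equal(rec$wacc, 1.0)
  expect_equal(rec$contribs$node_fraction[1], 1.0)  # root split
  # pure training labels: no split, empty contributions
  y_pure <- factor(rep("a", 40), levels = c("a", "b"))
  y_pure[1] <- "b"
  x_const <- cbind(g = rep(1, 40))
  rec2 <- evaluate_tree(x_const, y_pure, train_fraction = 0.66)
  expect_identical(nrow(rec2$contribs), 0L)
})

test_that("relative importance matches its one-term arithmetic", {
  rec <- list(wacc = 0.8,
              contribs = data.frame(feature = "f1", gain = 0.5,
                                    node_fraction = 1.0))
  ri <- relative_importance(list(rec), u = 1, v = 1,
                            feature_names = c("f1", "f2"))
  expect_equal(ri$ri[ri$gene == "f1"], 0.4)
  # absent feature gets RI 0 and ranks last
  expect_equal(ri$ri[ri$gene == "f2"], 0)
  expect_identical(ri$gene[2], "f2")
  # u = v = 0: RI is the plain sum of gains
  rec2 <- list(wacc = 0.5,
               contribs = data.frame(feature = c("f1", "f1"),
                                     gain = c(0.5, 0.25),
                                     node_fraction = c(1, 0.5)))
  ri2 <- relative_importance(list(rec2), u = 0, v = 0,
                             feature_names = "f1")
  expect_equal(ri2$ri, 0.75)
})

test_that("aggregated importances match a straight-line recomputation", {
  toy <- toy_separable(n_per_class = 15, seed = 53)
  set.seed(54)
  x <- cbind(toy$x, matrix(runif(45 * 8), 45, 8,
                           dimnames = list(NULL, paste0("n", 1:8))))
  for (params in list(list(s = 3, t = 3, u = 1, v = 1),
                      list(s = 2, t = 2, u = 2, v = 0.5),
                      list(s = 3, t = 1, u = 0, v = 0))) {
    cfg <- mcfs_config(d = 10, m = 3, s = params$s, t = params$t,
                       u = params$u, v = params$v, seed = 11)
    ranked <- run_mcfs(x, toy$y, cfg, keep_records = TRUE)
    oracle <- ri_oracle(attr(ranked, "records"), params$u, params$v,
                        colnames(x))
    expect_equal(setNames(ranked$ri, ranked$gene),
                 sort(oracle, decreasing = TRUE), tolerance = 1e-12)
    # and the standalone aggregator agrees with the streaming path
    via_records <- relative_importance(attr(ranked, "records"),
                                       u = params$u, v = params$v,
                                       feature_names = colnames(x))
    expect_equal(via_records$ri, unname(ranked$ri), tolerance = 1e-12)
    expect_identical(via_records$gene, ranked$gene)
  }
})

test_that("ranking is deterministic and restricted to projected features", {
  toy <- toy_separable(n_per_class = 10, seed = 55)
  cfg <- mcfs_config(d = 2, m = 1, s = 1, t = 1, seed = 5)
  a <- run_mcfs(toy$x, toy$y, cfg)
  b <- run_mcfs(toy$x, toy$y, cfg)
  expect_identical(a, b)
  # with s = t = 1 only the single projected feature can score above zero
  expect_identical(sum(a$ri > 0), 1L)

  cfg2 <- mcfs_config(d = 2, m = 2, s = 4, t = 2, seed = 6)
  expect_identical(run_mcfs(toy$x, toy$y, cfg2),
                   run_mcfs(toy$x, toy$y, cfg2))
})

test_that("planted markers outrank noise genes", {
  cfg_data <- synth_config(n_classes = 3, class_sizes = c(60, 90, 120),
                           n_genes = 60, markers_per_class = 4, seed = 8)
  sim <- simulate_profiles(cfg_data)
  cfg <- mcfs_config(d = 60, m = 6, s = 400, t = 2, seed = 8)
  ranked <- run_mcfs(sim$matrix, sim$labels, cfg)
  markers <- unlist(sim$truth$marker_map)
  marker_ranks <- match(markers, ranked$gene)
  noise_ranks <- match(sim$truth$noise_genes, ranked$gene)
  wt <- stats::wilcox.test(marker_ranks, noise_ranks,
                           alternative = "less")
  expect_lt(wt$p.value, 1e-6)
})

test_that("mcfs defaults follow the projection-coverage rule", {
  cfg <- mcfs_config(d = 100)
  expect_identical(cfg$m, 5L)                  # ceil(0.05 * 100)
  expect_identical(cfg$s, 6000L)               # ceil(300 * 100 / 5)
  expect_identical(cfg$t, 5L)
  expect_identical(mcfs_config(d = 10)$m, 1L)  # min 1
  expect_identical(mcfs_config(d = 10000, m = 10)$s, 20000L)  # cap binds
})
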