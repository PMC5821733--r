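single_tree_cfg <- forest_config(n_trees = 1, bootstrap = FALSE, seed = 1)

test_that("constant targets give all-zero importances, not an error", {
  x <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("A", "B")))
  m <- grn_forest(x, rep(3.7, 10), forest_config(n_trees = 5, seed = 1))
  expect_equal(unname(importance(m)), c(0, 0))
})

test_that("a single perfect split earns exactly the node variance reduction", {
  # y determined by input A on 4 rows {(0,0),(0,0),(1,1),(1,1)}:
  # importance(A) = 4 * Var({0,0,1,1}) = 1; B constant, importance 0
  x <- cbind(A = c(0, 0, 1, 1), B = c(0, 0, 0, 0))
  y <- c(0, 0, 1, 1)
  m <- grn_forest(x, y, single_tree_cfg)
  expect_equal(unname(importance(m)), c(1.0, 0))

  # with a bootstrap ensemble the perfect input still dominates
  m2 <- grn_forest(x, y, forest_config(n_trees = 100, seed = 2))
  imp <- importance(m2)
  expect_gte(imp[["A"]] / sum(imp), 0.99)
})

test_that("a hand-built two-level tree matches hand impurity accounting", {
  # outputs {0,1,2,3}; A splits {0,1}|{2,3}, B splits within each node:
  # I(A) = 4*1.25 - 2*0.25 - 2*0.25 = 4; I(B) = 0.5 + 0.5 = 1
  x <- cbind(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1))
  y <- c(0, 1, 2, 3)
  m <- grn_forest(x, y, single_tree_cfg)
  expect_equal(unname(importance(m)), c(4.0, 1.0))
})

test_that("one full tree's importances sum to the total output variation", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- matrix(runif(30 * 4), 30, 4,
                  dimnames = list(NULL, paste0("V", 1:4)))
      y <- runif(30)
    })
    m <- grn_forest(x, y, single_tree_cfg)
    n_var <- length(y) * mean((y - mean(y))^2) # population variance
    expect_equal(sum(importance(m)), n_var, tolerance = 1e-9)
  }

  # a duplicated irrelevant column shares importance without breaking
  # the conservation identity
  withr::with_seed(42, {
    x <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, c("A", "B", "B2")))
    x[, "B2"] <- x[, "B"]
    y <- runif(40)
  })
  m2 <- grn_forest(x, y, single_tree_cfg)
  expect_equal(sum(importance(m2)), 40 * mean((y - mean(y))^2),
               tolerance = 1e-9)
})

test_that("training is bit-deterministic under a fixed seed", {
  withr::with_seed(3, {
    x <- matrix(runif(25 * 3), 25, 3, dimnames = list(NULL, paste0("V", 1:3)))
    y <- runif(25)
  })
  cfg <- forest_config(n_trees = 50, k = 2, seed = 99)
  m1 <- grn_forest(x, y, cfg)
  m2 <- grn_forest(x, y, cfg)
  expect_identical(m1$tree_importance, m2$tree_importance)
  expect_identical(m1$inbag, m2$inbag)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("a single unbootstrapped tree memorizes its training sample", {
  withr::with_seed(4, {
    x <- matrix(runif(15 * 3), 15, 3, dimnames = list(NULL, paste0("V", 1:3)))
    y <- runif(15)
  })
  m <- grn_forest(x, y, single_tree_cfg)
  expect_equal(predict(m, x), y, tolerance = 1e-12)

  # constant-target forest predicts the constant everywhere
  mc <- grn_forest(x, rep(2.5, 15), forest_config(n_trees = 10, seed = 5))
  expect_equal(predict(mc, x), rep(2.5, 15))
})

test_that("out-of-bag predictions cover every row with enough trees", {
  withr::with_seed(6, {
    x <- matrix(runif(40 * 3), 40, 3, dimnames = list(NULL, paste0("V", 1:3)))
    y <- runif(40)
  })
  m <- grn_forest(x, y, forest_config(n_trees = 1000, seed = 7))
  oob <- predict_oob(m)
  expect_false(anyNA(oob))
  # every row really is out of bag for about T/e trees
  expect_gt(min(colSums(m$inbag == 0)), 0)
  expect_error(predict_oob(grn_forest(x, y, single_tree_cfg)), "bootstrap")
})

test_that("pure-noise inputs score below a perfectly predictive input", {
  wins <- 0L
  for (rep in 1:20) {
    withr::with_seed(rep, {
      x <- matrix(runif(30 * 4), 30, 4,
                  dimnames = list(NULL, c("signal", "n1", "n2", "n3")))
      y <- x[, "signal"]
    })
    m <- grn_forest(x, y, forest_config(n_trees = 30, seed = rep))
    imp <- importance(m)
    if (imp[["signal"]] > max(imp[c("n1", "n2", "n3")])) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("importance ranking agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  withr::with_seed(8, {
    x <- matrix(runif(60 * 5), 60, 5, dimnames = list(NULL, paste0("V", 1:5)))
    y <- 2 * x[, 1] + x[, 2] + 0.1 * rnorm(60)
  })
  mine <- importance(grn_forest(x, y, forest_config(n_trees = 300, seed = 1)))
  ref <- randomForest::randomForest(x, y, ntree = 300, mtry = 5, nodesize = 1)
  ref_imp <- randomForest::importance(ref)[, "IncNodePurity"]
  expect_equal(order(-mine), order(-ref_imp))
})

test_that("inputs and shapes are validated", {
  x <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(grn_forest(x[1, , drop = FALSE], 1), "2 samples")
  expect_error(grn_forest(unname(x), runif(5)), "column names")
  m <- grn_forest(x, runif(5), forest_config(n_trees = 2, seed = 1))
  expect_error(predict(m, matrix(1, 1, 3)), "3 columns")
  expect_error(predict(m, c(A = 1)), "lacks input genes")
})
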