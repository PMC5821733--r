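small_cfg <- function(seed = 1, n_trees = 50) forest_config(n_trees = n_trees,
                                                            seed = seed)

test_that("a perfect driver is top-ranked into its target", {
  hits <- 0L
  for (seed in 1:20) {
    fit <- dyngenie3(driver_series(seed = seed), decay = 0.3,
                     config = small_cfg(seed, 30))
    w <- fit$ranking$weights
    top_into_G2 <- names(which.max(w[, "G2"]))
    if (top_into_G2 == "G1" && w["G1", "G2"] > 0.8) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("weights are column-normalized with a zero diagonal", {
  fit <- dyngenie3(random_series(12, 4, seed = 2), decay = 0.5,
                   config = small_cfg(2))
  w <- fit$ranking$weights
  expect_equal(unname(diag(w)), rep(0, 4))
  expect_equal(unname(colSums(w)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(w >= 0))
})

test_that("non-candidate regulators get zero weight everywhere", {
  fit <- dyngenie3(random_series(12, 4, seed = 3), decay = 0.5,
                   regulators = c("G1", "G2"), config = small_cfg(3))
  w <- fit$ranking$weights
  expect_equal(unname(w["G3", ]), rep(0, 4))
  expect_equal(unname(w["G4", ]), rep(0, 4))
  expect_equal(unname(colSums(w[c("G1", "G2"), ])), rep(1, 4),
               tolerance = 1e-9)
  expect_error(dyngenie3(random_series(12, 4), decay = 0.5,
                         regulators = c("X1", "X2")),
               "disjoint")
})

test_that("constant expression yields an all-zero ranking with a warning", {
  s <- expression_series(0:5, matrix(1, 6, 3,
                                     dimnames = list(NULL, paste0("G", 1:3))))
  expect_warning(fit <- dyngenie3(s, decay = 0.5, config = small_cfg(1)),
                 "all-zero|zero")
  expect_equal(sum(fit$ranking$weights), 0)
})

test_that("static variant excludes the target from its own inputs", {
  ss <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("G", 1:4)))
  fit <- genie3(ss, config = small_cfg(4))
  expect_false("G1" %in% fit$models[["G1"]]$input_genes)
  expect_error(genie3(ss[1, , drop = FALSE]), "2 samples")

  # naive time-series mode is exactly static mode on stacked time points
  series <- list(random_series(8, 4, seed = 5), random_series(7, 4, seed = 6))
  stacked <- rbind(series[[1]]$values, series[[2]]$values)
  f1 <- genie3(series, config = small_cfg(7))
  f2 <- genie3(stacked, config = small_cfg(7))
  expect_identical(f1$ranking$weights, f2$ranking$weights)
})

test_that("dynamical and time-lagged rankings coincide at alpha = 1/dt", {
  dt <- 2.5
  series <- list(random_series(10, 4, seed = 8, dt = dt),
                 random_series(9, 4, seed = 9, dt = dt))
  cfg <- small_cfg(11, 40)
  dyn <- dyngenie3(series, decay = 1 / dt, config = cfg)
  lag <- genie3_lagged(series, config = cfg)
  expect_equal(dyn$ranking$weights, lag$ranking$weights, tolerance = 1e-9)
  expect_identical(rank_edges(dyn$ranking)[c("regulator", "target")],
                   rank_edges(lag$ranking)[c("regulator", "target")])
})

test_that("knockout z-scores follow the definition", {
  genes <- paste0("G", 1:3)
  ko <- matrix(0.7, 3, 3, dimnames = list(genes, genes))
  ko["G1", "G2"] <- 0.1 # deleting G1 drops G2 from 0.7 to 0.1
  wt <- c(G1 = 0.7, G2 = 0.7, G3 = 0.7)
  r <- mcz_ranking(ko, wt, sigma = c(G1 = 0.2, G2 = 0.2, G3 = 0.2))
  expect_equal(r$weights["G1", "G2"], 3.0) # |0.1 - 0.7| / 0.2
  expect_equal(r$weights["G2", "G3"], 0)   # knockout left the gene unchanged
  expect_equal(unname(diag(r$weights)), rep(0, 3))
  # deterministic
  r2 <- mcz_ranking(ko, wt, sigma = c(G1 = 0.2, G2 = 0.2, G3 = 0.2))
  expect_identical(r$weights, r2$weights)
  expect_error(mcz_ranking(ko[1:2, ], wt), "incomplete")
})

test_that("product combination behaves algebraically", {
  genes <- paste0("G", 1:3)
  mk <- function(v) structure(list(weights = matrix(v, 3, 3,
                                                    dimnames = list(genes, genes)),
                                   genes = genes, regulators = genes,
                                   method = "m"),
                              class = "link_ranking")
  a <- mk(runif(9)); b <- mk(1); z <- mk(0)
  expect_equal(combine_rankings(a, b)$weights, a$weights)
  expect_equal(sum(combine_rankings(a, z)$weights), 0)
  expect_equal(combine_rankings(a, b)$weights, combine_rankings(b, a)$weights)
})

test_that("edge ranking is ordered, tie-stable and complete", {
  genes <- paste0("G", 1:3)
  w <- matrix(0, 3, 3, dimnames = list(genes, genes))
  w["G1", "G2"] <- 0.9; w["G2", "G1"] <- 0.1
  r <- structure(list(weights = w, genes = genes, regulators = genes,
                      method = "m"), class = "link_ranking")
  e <- rank_edges(r)
  expect_equal(nrow(e), 6)
  expect_equal(e$regulator[1:2], c("G1", "G2"))
  # the four zero-weight edges are in lexicographic order
  expect_equal(paste(e$regulator[3:6], e$target[3:6]),
               sort(paste(e$regulator[3:6], e$target[3:6])))
})

test_that("gene-name-keyed seeds make results order-independent", {
  s <- random_series(10, 4, seed = 12)
  fit <- dyngenie3(s, decay = 0.5, config = small_cfg(13))
  perm <- c(3, 1, 4, 2)
  s_perm <- expression_series(s$times, s$values[, perm], label = s$label)
  fit_perm <- dyngenie3(s_perm, decay = 0.5, config = small_cfg(13))
  expect_equal(fit_perm$ranking$weights[rownames(fit$ranking$weights),
                                        colnames(fit$ranking$weights)],
               fit$ranking$weights, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- dyngenie3(random_series(8, 3, seed = 14), decay = 0.5,
                   config = small_cfg(14, 20))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  g <- glance(fit)
  expect_equal(g$n_genes, 3L)
  expect_equal(g$n_samples, 7L)
  expect_equal(g$method, "dyngenie3")
})
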