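ranked_tbl <- function(regs, tgts, w = NULL) {
  tibble::tibble(regulator = regs, target = tgts,
                 weight = if (is.null(w)) rev(seq_along(regs)) else w)
}

test_that("precision-recall points and area follow the prefix convention", {
  # eligible pairs: regulators {A,B} x genes {A,B,C} minus self = 4 pairs
  genes <- c("A", "B", "C"); regs <- c("A", "B")
  ranked <- ranked_tbl(c("A", "B", "A", "B"), c("B", "A", "C", "C"))
  gold <- tibble::tibble(regulator = c("A", "A"), target = c("B", "C"))
  pr <- pr_curve(ranked, gold, genes = genes, regulators = regs)
  # positives at ranks 1 and 3: precisions 1/1, 1/2, 2/3, 2/4
  expect_equal(pr$curve$precision, c(1, 1/2, 2/3, 2/4))
  expect_equal(pr$curve$recall, c(0.5, 0.5, 1, 1))
  # trapezoids: rank-1 positive contributes 1/2; the rank-3 positive
  # spans precision 1/2 (rank 2) to 2/3 (rank 3): (1/2 + 2/3)/2 * 1/2
  expect_equal(pr$aupr, (1 + (1/2 + 2/3) / 2) / 2, tolerance = 1e-12)

  # all positives first: perfect area
  perfect <- ranked_tbl(c("A", "A", "B", "B"), c("B", "C", "A", "C"))
  expect_equal(pr_curve(perfect, gold, genes = genes, regulators = regs)$aupr,
               1.0)
  expect_error(pr_curve(perfect, gold[0, ], genes = genes, regulators = regs),
               "empty")
})

test_that("unranked eligible pairs are appended and stray gold edges dropped", {
  genes <- c("A", "B", "C")
  partial <- ranked_tbl("A", "B") # 5 other eligible pairs unranked
  gold <- tibble::tibble(regulator = c("A", "C"), target = c("B", "A"))
  pr <- pr_curve(partial, gold, genes = genes)
  expect_equal(pr$eligible_pairs, 6)
  expect_equal(pr$positives, 2)

  gold_stray <- tibble::tibble(regulator = c("A", "A"), target = c("B", "A"))
  expect_warning(pr2 <- pr_curve(partial, gold_stray, genes = genes),
                 "outside the eligible")
  expect_equal(pr2$positives, 1)
})

test_that("the area matches a brute-force prefix oracle exhaustively", {
  # every positive/negative labelling of rankings of up to 8 edges
  for (n in c(4, 6, 8)) {
    for (mask in 1:(2^n - 2)) {
      is_pos <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      got <- grndyn:::aupr_from_positive_ranks(which(is_pos), sum(is_pos))
      expect_equal(got, aupr_oracle(is_pos), tolerance = 1e-12)
    }
  }
})

test_that("a random ranking's mean area is close to the positive fraction", {
  sig <- aupr_significance(0.5, n_pairs = 100, n_pos = 10,
                           null_samples = 1000, seed = 5)
  expect_lt(abs(mean(sig$null) - 0.10), 0.03)
})

test_that("significance and score aggregation behave as defined", {
  expect_equal(aupr_score(c(0.1, 0.1)), 1.0)
  expect_equal(aupr_score(c(1, 1, 1)), 0)
  expect_error(aupr_score(c(0, 0.5)), "p > 0")

  # an observed area below the null median is unimpressive
  sig <- aupr_significance(0.08, n_pairs = 100, n_pos = 10,
                           null_samples = 2000, seed = 6)
  expect_gt(sig$p, 0.4)
  expect_false(sig$extrapolated)

  # an unbeatable observation falls back to the fitted tail, flagged
  sig2 <- aupr_significance(1.0, n_pairs = 500, n_pos = 10,
                            null_samples = 500, seed = 7)
  expect_true(sig2$extrapolated)
  expect_lte(sig2$p, 1 / 501)
  expect_gt(sig2$p, 0)

  # monotone: a larger observed area never gets a larger p
  p_seq <- vapply(c(0.2, 0.4, 0.8), function(a) {
    aupr_significance(a, 100, 10, null_samples = 2000, seed = 8)$p
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 0))
})

test_that("top-k overlap and its null match the hypergeometric law", {
  genes <- c("A", "B", "C")
  ranked <- ranked_tbl(c("A", "B", "A"), c("B", "A", "C"))
  gold <- tibble::tibble(regulator = c("A", "B"), target = c("B", "A"))
  expect_equal(topk_overlap(ranked, gold, k = 2), 2) # gold within top k
  expect_equal(topk_overlap(ranked, gold, k = 1), 1)

  # mean of the sampled null: k * gold / eligible within 3 standard errors
  null <- topk_null(n_eligible = 100, n_gold = 10, k = 20, draws = 10000,
                    seed = 9)$null
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - 20 * 10 / 100), 3 * se)

  # empirical tail vs the exact hypergeometric tail on a small instance
  res <- topk_null(n_eligible = 20, n_gold = 5, k = 6, observed = 3,
                   draws = 10000, seed = 10)
  p_exact <- phyper(2, 5, 15, 6, lower.tail = FALSE)
  se_p <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p - p_exact), 3 * se_p)
})

test_that("tree-stability score matches its pairwise-overlap definition", {
  fake_fit <- function(imp, target = "T") {
    structure(list(genes = target,
                   models = stats::setNames(
                     list(list(tree_importance = imp)), target)),
              class = "grn_fit")
  }
  cands <- paste0("R", 1:10)
  # two trees whose top-5 sets intersect in exactly 2 candidates -> 2/5
  t1 <- c(10, 9, 8, 7, 6, 0, 0, 0, 0, 0) # top5 = R1..R5
  t2 <- c(5, 4, 0, 0, 0, 10, 9, 8, 0, 0) # top5 = R6,R7,R8,R1,R2
  imp <- matrix(c(t1, t2), ncol = 2,
                dimnames = list(cands, NULL))
  imp <- rbind(imp, T = c(99, 99)) # the target's own row is excluded
  expect_equal(stability_score(fake_fit(imp)), 0.4)

  # identical trees give a perfect score
  imp_same <- matrix(rep(t1, 4), ncol = 4, dimnames = list(cands, NULL))
  expect_equal(stability_score(fake_fit(imp_same)), 1.0)

  # with exactly m candidates every top set is the full candidate set
  imp5 <- matrix(runif(15), 5, 3, dimnames = list(paste0("R", 1:5), NULL))
  expect_equal(stability_score(fake_fit(imp5)), 1.0)

  expect_error(stability_score(fake_fit(imp5), top_m = 6), "at least")
  # invariant to tree order
  expect_equal(stability_score(fake_fit(imp[, c(2, 1)])), 0.4)
})

test_that("stability approaches 1 as ensembles agree on the regulators", {
  # a strongly driven target: most trees put the driver in their top set
  fit <- dyngenie3(driver_series(n = 30, seed = 31), decay = 0.3,
                   config = forest_config(n_trees = 30, seed = 31))
  s <- stability_score(fit, top_m = 2)
  expect_gte(s, 0.5)
  expect_lte(s, 1)
})
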