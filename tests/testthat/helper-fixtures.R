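# Fixtures are built in code; nothing is read from disk except what a
# test writes itself.

# A tiny deterministic series: p genes, n points, values from a seeded
# uniform draw (continuous, so split ties never occur).
random_series <- function(n = 8, p = 3, seed = 1, dt = 1, label = "s") {
  withr::with_seed(seed, {
    vals <- matrix(runif(n * p, 0, 2), n, p,
                   dimnames = list(NULL, paste0("G", seq_len(p))))
    expression_series(dt * (seq_len(n) - 1), vals, label = label)
  })
}

# Series in which G1 alone drives G2's increments through the exact
# finite-difference law, G3 is independent noise: the regression target
# for G2 equals x1(t_k) exactly.
driver_series <- function(n = 20, alpha2 = 0.3, dt = 1, seed = 1) {
  withr::with_seed(seed, {
    x1 <- runif(n, 0.2, 2)
    x3 <- runif(n, 0.2, 2)
    x2 <- numeric(n)
    x2[1] <- 1
    for (k in seq_len(n - 1)) {
      x2[k + 1] <- x2[k] + dt * (x1[k] - alpha2 * x2[k])
    }
    expression_series(dt * (seq_len(n) - 1),
                      cbind(G1 = x1, G2 = x2, G3 = x3),
                      label = "driver")
  })
}

# Hand-built fit whose per-gene "forests" predict a constant: trained on
# constant targets, every tree is a stump predicting c.
constant_fit <- function(c_by_gene, alpha_by_gene) {
  genes <- names(c_by_gene)
  models <- lapply(genes, function(j) {
    x <- matrix(runif(10 * length(genes)), 10,
                dimnames = list(NULL, genes))
    m <- grn_forest(x, rep(c_by_gene[[j]], 10),
                    forest_config(n_trees = 3, bootstrap = FALSE, seed = 1))
    m$alpha <- alpha_by_gene[[j]]
    m$learning_sample <- list(dt = rep(1, 10))
    m
  })
  names(models) <- genes
  structure(list(models = models, genes = genes, regulators = genes,
                 alpha = alpha_by_gene, method = "dyngenie3",
                 config = forest_config(n_trees = 3, seed = 1)),
            class = "grn_fit")
}

# Independent prefix-enumeration AUPR oracle: build the (recall,
# precision) point for every rank prefix, start the polyline at recall 0
# with the first prefix's precision, and integrate by trapezoid over
# recall. Segments between positives have zero recall width.
aupr_oracle <- function(is_positive) {
  n_pos <- sum(is_positive)
  stopifnot(n_pos >= 1)
  tp <- cumsum(is_positive)
  n <- length(is_positive)
  rec <- c(0, tp / n_pos)
  prec <- c(tp[1] / 1, tp / seq_len(n))
  area <- 0
  for (i in seq_len(n)) {
    area <- area + (rec[i + 1] - rec[i]) * (prec[i + 1] + prec[i]) / 2
  }
  area
}
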