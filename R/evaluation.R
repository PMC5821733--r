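# Scoring rankings against gold standards. The AUPR convention:
# trapezoidal integration over the (recall, precision) points of every
# rank prefix, with the polyline started at recall 0 at the first
# prefix's precision. Flat-recall runs between positives contribute no
# width, so each positive adds one trapezoid between the precision just
# before it and the precision at it. A perfect ranking gives exactly 1;
# a random ranking averages close to the positive fraction.

edge_key <- function(regulator, target) paste(regulator, target, sep = "\r")

eligible_pairs <- function(genes, regulators = NULL) {
  if (is.null(regulators)) regulators <- genes
  pairs <- tidyr::expand_grid(regulator = regulators, target = genes)
  dplyr::filter(pairs, .data$regulator != .data$target)
}

# AUPR from the sorted ranks of the positives; every positive must be
# ranked (zero-weight edges are appended to rankings, so it always is).
# Recall only moves at a positive, so the trapezoid arriving at the
# m-th positive spans the precision at the preceding prefix,
# (m-1)/(k_m - 1), and the precision at the positive itself, m/k_m; a
# positive at rank 1 contributes a full-height rectangle (the polyline
# starts at (0, 1) in that case).
aupr_from_positive_ranks <- function(pos_ranks, n_pos) {
  stopifnot(n_pos >= 1L, length(pos_ranks) == n_pos)
  k <- sort(pos_ranks)
  m <- seq_len(n_pos)
  p_at <- m / k
  p_before <- ifelse(k == 1L, 1, (m - 1) / pmax(k - 1L, 1L))
  sum((p_before + p_at) / 2) / n_pos
}

#' Precision-recall curve and AUPR of a ranked edge list
#'
#' Ranks are scored against a gold standard over the eligible pair set
#' (candidate regulators x genes, minus self-pairs). Eligible pairs
#' absent from the ranking are appended after all ranked edges in
#' deterministic lexicographic order with weight 0, so every method
#' ranks the same pair set; gold edges outside the eligible set are
#' dropped with a warning.
#'
#' @param ranked A `link_ranking`, a `grn_fit`, or the tibble from
#'   [rank_edges()] (de-duplicated).
#' @param gold Gold-standard edges: tibble/data frame with columns
#'   `regulator`, `target`.
#' @param genes Gene universe; taken from `ranked` when it is a ranking
#'   object.
#' @param regulators Candidate regulators defining the eligible pairs;
#'   taken from `ranked` when available, else all genes.
#' @return A `pr_result`: list with `curve` (tibble `rank`, `recall`,
#'   `precision` at every prefix), `aupr`, `positives`,
#'   `eligible_pairs`.
#' @export
pr_curve <- function(ranked, gold, genes = NULL, regulators = NULL) {
  if (inherits(ranked, "grn_fit")) ranked <- ranked$ranking
  if (inherits(ranked, "link_ranking")) {
    genes <- ranked$genes
    regulators <- ranked$regulators
    ranked <- rank_edges(ranked)
  }
  stopifnot(all(c("regulator", "target") %in% names(ranked)))
  if (is.null(genes)) genes <- sort(unique(c(ranked$regulator, ranked$target,
                                             gold$regulator, gold$target)))
  pairs <- eligible_pairs(genes, regulators)
  pair_keys <- edge_key(pairs$regulator, pairs$target)
  rank_keys <- edge_key(ranked$regulator, ranked$target)
  if (anyDuplicated(rank_keys)) stop("ranking contains duplicate edges")
  rank_keys <- rank_keys[rank_keys %in% pair_keys]
  missing <- setdiff(pair_keys, rank_keys)
  if (length(missing) > 0L) rank_keys <- c(rank_keys, sort(missing))

  gold_keys <- unique(edge_key(gold$regulator, gold$target))
  outside <- setdiff(gold_keys, pair_keys)
  if (length(outside) > 0L) {
    warning("dropping ", length(outside),
            " gold edge(s) outside the eligible pair set")
    gold_keys <- setdiff(gold_keys, outside)
  }
  n_pos <- length(gold_keys)
  if (n_pos == 0L) stop("gold standard is empty over the eligible pairs")

  is_pos <- rank_keys %in% gold_keys
  tp <- cumsum(is_pos)
  n <- length(rank_keys)
  curve <- tibble::tibble(rank = seq_len(n), recall = tp / n_pos,
                          precision = tp / seq_len(n))
  structure(list(curve = curve,
                 aupr = aupr_from_positive_ranks(which(is_pos), n_pos),
                 positives = n_pos, eligible_pairs = n),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat("Precision-recall result: AUPR = ", format(x$aupr, digits = 4),
      " (", x$positives, " positives / ", x$eligible_pairs,
      " eligible pairs; random expectation ~ ",
      format(x$positives / x$eligible_pairs, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' AUPR accessor
#' @param x A `pr_result`.
#' @return The area under the precision-recall curve.
#' @export
aupr <- function(x) {
  stopifnot(inherits(x, "pr_result"))
  x$aupr
}

#' Probability that a random ranking reaches an observed AUPR
#'
#' Monte-Carlo estimate: positions of the positives are drawn uniformly
#' without replacement among the eligible pairs, the null AUPR computed
#' for each draw, and the tail probability estimated as
#' \eqn{(\#\{null \ge observed\} + 1)/(draws + 1)}. When the observed
#' AUPR exceeds every null draw the tail is extrapolated from a
#' log-normal fit to the null sample (and flagged as such) — an internal
#' stand-in for the unpublished tail model of the original benchmark
#' scoring.
#'
#' @param observed Observed AUPR.
#' @param n_pairs Number of eligible pairs.
#' @param n_pos Number of gold-standard positives.
#' @param null_samples Number of random rankings (default 100000).
#' @param seed Integer seed.
#' @return List with `p`, `extrapolated`, and the `null` AUPR sample.
#' @export
aupr_significance <- function(observed, n_pairs, n_pos,
                              null_samples = 100000L, seed = 42L) {
  stopifnot(n_pos >= 1L, n_pairs >= n_pos)
  null <- withr::with_seed(seed, {
    vapply(seq_len(null_samples), function(i) {
      aupr_from_positive_ranks(sample.int(n_pairs, n_pos), n_pos)
    }, numeric(1))
  })
  n_ge <- sum(null >= observed)
  extrapolated <- n_ge == 0L
  p <- if (extrapolated) {
    lnull <- log(null)
    min(stats::plnorm(observed, mean(lnull), stats::sd(lnull),
                      lower.tail = FALSE),
        1 / (null_samples + 1))
  } else {
    (n_ge + 1) / (null_samples + 1)
  }
  list(p = p, extrapolated = extrapolated, null = null)
}

#' Aggregate AUPR significances into a single benchmark score
#'
#' \deqn{score = -\frac{1}{n}\sum_i \log_{10} p^{(i)},}
#' the mean number of orders of magnitude by which each network's AUPR
#' beats a random ranking.
#'
#' @param p Vector of per-network tail probabilities in (0, 1].
#' @return The score (0 when every p is 1).
#' @export
aupr_score <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1))
  -mean(log10(p))
}

#' Overlap between the top-k predicted edges and the gold standard
#'
#' @param ranked A `link_ranking`, `grn_fit` or [rank_edges()] tibble.
#' @param gold Gold-standard edge tibble (`regulator`, `target`).
#' @param k Number of top edges considered (500 in the usual convention).
#' @return Integer overlap count.
#' @export
topk_overlap <- function(ranked, gold, k = 500L) {
  if (inherits(ranked, "grn_fit")) ranked <- ranked$ranking
  if (inherits(ranked, "link_ranking")) ranked <- rank_edges(ranked)
  top <- utils::head(ranked, k)
  sum(edge_key(top$regulator, top$target) %in%
        unique(edge_key(gold$regulator, gold$target)))
}

#' Null distribution of the top-k overlap under random networks
#'
#' Draws random "top-k" sets of k edges uniformly without replacement
#' from the eligible pairs and counts their overlap with the gold
#' standard; the empirical tail probability of an observed overlap is
#' \eqn{(\#\{null \ge observed\} + 1)/(draws + 1)}. (The null is
#' hypergeometric; the simulation keeps the check honest against the
#' closed form.)
#'
#' @param n_eligible Number of eligible pairs.
#' @param n_gold Number of gold edges among them.
#' @param k Size of the top set.
#' @param observed Optional observed overlap for which to report `p`.
#' @param draws Number of random networks (default 10000).
#' @param seed Integer seed.
#' @return List with `null` (integer vector of overlaps) and, when
#'   `observed` is given, `p`.
#' @export
topk_null <- function(n_eligible, n_gold, k, observed = NULL,
                      draws = 10000L, seed = 42L) {
  stopifnot(k <= n_eligible, n_gold <= n_eligible)
  null <- withr::with_seed(seed, {
    vapply(seq_len(draws), function(i) {
      sum(sample.int(n_eligible, k) <= n_gold)
    }, numeric(1))
  })
  out <- list(null = null)
  if (!is.null(observed)) out$p <- (sum(null >= observed) + 1) / (draws + 1)
  out
}

#' Tree-stability score of a fitted network
#'
#' How consistently the individual trees of each gene's ensemble agree
#' on that gene's main regulators: for every tree, the top `top_m`
#' candidates by that single tree's importance (the gene itself
#' excluded, ties broken by input order); the score is the mean over
#' genes and over all tree pairs of the fractional overlap
#' \eqn{|S_i \cap S_{i'}|/m}. Ranges from near 0 (trees disagree
#' entirely) to 1 (all trees rank the same regulators on top); used to
#' compare candidate decay-rate settings.
#'
#' @param fit A `grn_fit` whose ensembles have at least 2 trees.
#' @param top_m Size of the per-tree top set (default 5).
#' @return A scalar in \eqn{[0, 1]}.
#' @export
stability_score <- function(fit, top_m = 5L) {
  stopifnot(inherits(fit, "grn_fit"))
  top_m <- as.integer(top_m)
  per_gene <- vapply(fit$genes, function(j) {
    model <- fit$models[[j]]
    imp <- model$tree_importance
    imp <- imp[setdiff(rownames(imp), j), , drop = FALSE]
    n_cand <- nrow(imp)
    if (n_cand < top_m) {
      stop("gene ", j, " has ", n_cand, " candidate regulators; ",
           "stability_score needs at least top_m = ", top_m)
    }
    T <- ncol(imp)
    if (T < 2L) stop("stability_score needs at least 2 trees per ensemble")
    # n_c = number of trees whose top-m set contains candidate c;
    # sum over tree pairs of |S_i n S_i'| = sum_c choose(n_c, 2)
    counts <- integer(n_cand)
    for (t in seq_len(T)) {
      top <- order(-imp[, t])[seq_len(top_m)]
      counts[top] <- counts[top] + 1L
    }
    sum(choose(counts, 2)) / (choose(T, 2) * top_m)
  }, numeric(1))
  mean(per_gene)
}
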