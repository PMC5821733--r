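# Per-gene forests -> ranked network. All methods fill a p x p weight
# matrix (rows = regulators, columns = targets), zero the diagonal, zero
# non-candidate rows, and normalize each informative column to sum 1 so
# importances are comparable across target genes.

# Deterministic per-gene seed derived from the master seed and the gene
# name (not its position), so results are independent of the order in
# which genes are processed. Plain 31-bit polynomial hash.
gene_seed <- function(master_seed, gene) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(gene)) h <- (h * 131 + b) %% m
  (as.double(master_seed) * 2654435761 + h) %% m
}

new_link_ranking <- function(weights, regulators, method) {
  genes <- colnames(weights)
  stopifnot(identical(rownames(weights), genes))
  structure(list(weights = weights, genes = genes, regulators = regulators,
                 method = method),
            class = "link_ranking")
}

# Zero diagonal + non-candidate rows, then divide each column by its sum
# over eligible regulators. Columns with no signal stay all-zero (no
# evidence is not uniform evidence).
normalize_weights <- function(weights, regulators) {
  genes <- colnames(weights)
  weights[setdiff(genes, regulators), ] <- 0
  diag(weights) <- 0
  sums <- colSums(weights)
  pos <- sums > 0
  weights[, pos] <- sweep(weights[, pos, drop = FALSE], 2, sums[pos], "/")
  if (!any(pos)) {
    warning("all importances are zero (constant expression?); ",
            "emitting an all-zero ranking")
  }
  weights
}

check_regulators <- function(regulators, genes) {
  if (is.null(regulators)) return(genes)
  if (length(intersect(regulators, genes)) == 0L) {
    stop("candidate regulator list is disjoint from the gene set")
  }
  unknown <- setdiff(regulators, genes)
  if (length(unknown) > 0L) {
    stop("unknown candidate regulators: ", paste(unknown, collapse = ", "))
  }
  genes[genes %in% regulators]
}

resolve_alpha <- function(decay, genes, series) {
  if (is.character(decay) && length(decay) == 1L && decay == "data_derived") {
    est <- estimate_decay_rates(series)
    return(stats::setNames(est$alpha, est$gene))
  }
  if (is.data.frame(decay)) decay <- stats::setNames(decay$alpha, decay$gene)
  if (is.numeric(decay) && length(decay) == 1L && is.null(names(decay))) {
    decay <- stats::setNames(rep(decay, length(genes)), genes)
  }
  if (!is.numeric(decay) || is.null(names(decay))) {
    stop("`decay` must be \"data_derived\", a single rate, a named vector, ",
         "or a tibble with columns gene/alpha")
  }
  missing <- setdiff(genes, names(decay))
  if (length(missing) > 0L) {
    stop("no decay rate for gene(s): ", paste(missing, collapse = ", "))
  }
  if (any(decay[genes] <= 0)) stop("decay rates must be positive")
  decay[genes]
}

fit_gene_models <- function(build_sample, genes, config) {
  models <- vector("list", length(genes))
  names(models) <- genes
  for (j in genes) {
    ls_j <- build_sample(j)
    cfg_j <- config
    cfg_j$seed <- gene_seed(config$seed, j)
    model <- grn_forest(ls_j$inputs, ls_j$targets, cfg_j)
    model$learning_sample <- ls_j
    models[[j]] <- model
  }
  models
}

weights_from_models <- function(models, genes, regulators) {
  weights <- matrix(0, length(genes), length(genes),
                    dimnames = list(genes, genes))
  for (j in names(models)) {
    imp <- importance(models[[j]])
    weights[names(imp), j] <- imp
  }
  normalize_weights(weights, regulators)
}

#' Infer a regulatory network from time series (and steady-state) data
#'
#' The dynamical variant of the tree-ensemble network inference
#' framework: each gene's trajectory is modelled by the ODE
#' \eqn{dx_j/dt = -\alpha_j x_j + f_j(x)}, the transcription function
#' \eqn{f_j} is learned as a Random forest on the finite-difference
#' learning sample (time-series rows, plus steady-state rows
#' \eqn{(x(e_k), \alpha_j x_j(e_k))} when `ss` is supplied), and the
#' regulators of each gene are ranked by the forest's variance-reduction
#' importance scores, self-links zeroed and each target's scores
#' normalized to sum 1.
#'
#' Genes are fitted independently with per-gene seeds derived from the
#' master seed and the gene name, so the result does not depend on
#' processing order.
#'
#' @param series An [expression_series()] or list of them.
#' @param ss Optional steady-state matrix (conditions x genes).
#' @param decay `"data_derived"` (estimate rates from the series, the
#'   default), a single rate, a named per-gene vector, or the tibble
#'   from [read_decay_rates()]/[estimate_decay_rates()].
#' @param regulators Optional candidate regulator names; default all genes.
#' @param config A [forest_config()].
#' @return A `grn_fit`: list with `ranking` (a `link_ranking`), `models`
#'   (per-gene `grn_forest` with its learning sample), `alpha`, `genes`,
#'   `regulators`, `method` and `config`.
#' @examples
#' net <- sample_network(5, avg_degree = 1.5, seed = 1)
#' data <- simulate_dataset(net, n_series = 2, n_points = 11, seed = 1)
#' fit <- dyngenie3(data$series, config = forest_config(n_trees = 50, seed = 1))
#' rank_edges(fit$ranking)
#' @export
dyngenie3 <- function(series, ss = NULL, decay = "data_derived",
                      regulators = NULL, config = forest_config()) {
  series <- as_series_list(series)
  genes <- series_genes(series)
  regulators <- check_regulators(regulators, genes)
  alpha <- resolve_alpha(decay, genes, series)
  if (!is.null(ss)) {
    ss <- as.matrix(ss)
    ss <- align_genes(ss, genes, "steady-state matrix")
  }
  models <- fit_gene_models(function(j) {
    ls_ts <- build_ts_learning_sample(series, j, alpha[[j]], regulators)
    ls_ss <- if (is.null(ss)) NULL
             else build_ss_learning_sample(ss, j, alpha[[j]], regulators)
    merge_learning_samples(ls_ts, ls_ss)
  }, genes, config)
  for (j in genes) models[[j]]$alpha <- alpha[[j]]
  weights <- weights_from_models(models, genes, regulators)
  structure(
    list(ranking = new_link_ranking(weights, regulators, "dyngenie3"),
         models = models, alpha = alpha, genes = genes,
         regulators = regulators, method = "dyngenie3", config = config),
    class = "grn_fit"
  )
}

#' Infer a network from independent expression samples (static variant)
#'
#' The original steady-state formulation: each gene's expression in a
#' condition is modelled as a function of the other genes' expression in
#' the same condition, \eqn{x_j = f_j(x_{-j})}; the target gene is
#' excluded from its own inputs. Time series may be supplied, in which
#' case the time points are naively treated as independent conditions.
#'
#' @param data Conditions x genes matrix, or an [expression_series()]
#'   (or list of them) whose time points are stacked as conditions.
#' @inheritParams dyngenie3
#' @return A `grn_fit` (see [dyngenie3()]), `method = "genie3"`.
#' @export
genie3 <- function(data, regulators = NULL, config = forest_config()) {
  if (inherits(data, "expression_series") ||
      (is.list(data) && !is.data.frame(data) && !is.matrix(data))) {
    series <- as_series_list(data)
    data <- do.call(rbind, lapply(series, `[[`, "values"))
  }
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("`data` must have gene names as columns")
  if (nrow(data) < 2L) stop("at least 2 samples are required")
  genes <- colnames(data)
  regulators <- check_regulators(regulators, genes)
  models <- fit_gene_models(function(j) {
    inputs_genes <- resolve_inputs(genes, j, regulators, include_target = FALSE)
    if (length(inputs_genes) == 0L) {
      stop("no candidate regulators left for gene ", j)
    }
    new_learning_sample(data[, inputs_genes, drop = FALSE], data[, j], j,
                        origin = rep("steady_state", nrow(data)),
                        x_prev = rep(NA_real_, nrow(data)),
                        dt = rep(NA_real_, nrow(data)),
                        x_next = rep(NA_real_, nrow(data)))
  }, genes, config)
  weights <- weights_from_models(models, genes, regulators)
  structure(
    list(ranking = new_link_ranking(weights, regulators, "genie3"),
         models = models, alpha = NULL, genes = genes,
         regulators = regulators, method = "genie3", config = config),
    class = "grn_fit"
  )
}

#' Time-lagged static variant
#'
#' Static learning on lagged pairs: inputs are the full expression state
#' at \eqn{t_k} (including the target gene) and the output is the
#' target's expression at \eqn{t_{k+1}}. With a uniform sampling
#' interval \eqn{\Delta t} this coincides with the dynamical variant run
#' at \eqn{\alpha_j = 1/\Delta t}: the regression targets differ only by
#' the positive factor \eqn{1/\Delta t}, which cannot change any
#' variance-reduction split, so under a shared seed the rankings are
#' identical.
#'
#' @inheritParams dyngenie3
#' @return A `grn_fit`, `method = "genie3_lagged"`.
#' @export
genie3_lagged <- function(series, regulators = NULL, config = forest_config()) {
  series <- as_series_list(series)
  genes <- series_genes(series)
  regulators <- check_regulators(regulators, genes)
  models <- fit_gene_models(function(j) {
    inputs_genes <- resolve_inputs(genes, j, regulators, include_target = TRUE)
    rows <- list(); y <- numeric(0)
    for (s in series) {
      n <- length(s$times)
      k <- seq_len(n - 1L)
      rows[[length(rows) + 1L]] <- s$values[k, inputs_genes, drop = FALSE]
      y <- c(y, s$values[k + 1L, j])
    }
    inputs <- do.call(rbind, rows)
    rownames(inputs) <- NULL
    m <- length(y)
    new_learning_sample(inputs, y, j, origin = rep("time_series", m),
                        x_prev = rep(NA_real_, m), dt = rep(NA_real_, m),
                        x_next = rep(NA_real_, m))
  }, genes, config)
  weights <- weights_from_models(models, genes, regulators)
  structure(
    list(ranking = new_link_ranking(weights, regulators, "genie3_lagged"),
         models = models, alpha = NULL, genes = genes,
         regulators = regulators, method = "genie3_lagged", config = config),
    class = "grn_fit"
  )
}

#' Median-corrected z-scores from systematic knockouts
#'
#' Ranks the edge \eqn{i \to j} by how much deleting gene \eqn{i} moves
#' gene \eqn{j} away from its wild-type expression, in units of gene
#' \eqn{j}'s variability:
#' \deqn{w_{i,j} = |x^j_{i,ko} - x^j_{wt}| / \sigma_j.}
#' By default \eqn{\sigma_j} is the standard deviation of gene \eqn{j}
#' over all provided steady-state observations (wild type plus every
#' knockout); genes with zero variability are excluded with a warning.
#'
#' @param ko_values p x p matrix, row i = steady state after deleting
#'   gene i (as from [read_knockout_matrix()]).
#' @param wild_type Named wild-type expression vector.
#' @param sigma Optional named per-gene standard deviations overriding
#'   the default.
#' @return A `link_ranking`, `method = "mcz"`.
#' @export
mcz_ranking <- function(ko_values, wild_type, sigma = NULL) {
  ko_values <- as.matrix(ko_values)
  genes <- colnames(ko_values)
  if (is.null(genes)) stop("`ko_values` must have gene names as columns")
  missing <- setdiff(genes, rownames(ko_values))
  if (length(missing) > 0L) {
    stop("knockout matrix is incomplete; no knockout row for gene(s): ",
         paste(missing, collapse = ", "))
  }
  ko_values <- ko_values[genes, , drop = FALSE]
  wild_type <- wild_type[genes]
  if (anyNA(wild_type)) stop("`wild_type` must cover every gene")
  if (is.null(sigma)) {
    sigma <- apply(rbind(wild_type, ko_values), 2, stats::sd)
  } else {
    sigma <- sigma[genes]
    if (anyNA(sigma)) stop("`sigma` must cover every gene")
  }
  dead <- sigma <= 0
  if (any(dead)) {
    warning("zero expression variability for gene(s) ",
            paste(genes[dead], collapse = ", "),
            "; their incoming edges get weight 0")
  }
  weights <- abs(sweep(ko_values, 2, wild_type, "-"))
  weights <- sweep(weights, 2, ifelse(dead, Inf, sigma), "/")
  diag(weights) <- 0
  new_link_ranking(weights, genes, "mcz")
}

#' Combine two link rankings by elementwise product
#'
#' The combined weight of an edge is the product of its weights under
#' the two methods, so only edges top-ranked by both stay top-ranked.
#' No renormalization is applied.
#'
#' @param a,b `link_ranking` objects over the same genes and candidate
#'   regulators.
#' @return A `link_ranking`.
#' @export
combine_rankings <- function(a, b) {
  stopifnot(inherits(a, "link_ranking"), inherits(b, "link_ranking"))
  if (!identical(a$genes, b$genes)) stop("rankings cover different gene sets")
  if (!identical(a$regulators, b$regulators)) {
    stop("rankings have different candidate regulator sets")
  }
  new_link_ranking(a$weights * b$weights, a$regulators,
                   paste0(a$method, "*", b$method))
}

#' Ordered edge list of a link ranking
#'
#' All candidate (regulator, target) pairs except self-links, sorted by
#' decreasing weight with deterministic lexicographic tie-breaking.
#'
#' @param ranking A `link_ranking`.
#' @return Tibble with columns `regulator`, `target`, `weight`.
#' @export
rank_edges <- function(ranking) {
  stopifnot(inherits(ranking, "link_ranking"))
  w <- ranking$weights
  edges <- tidyr::expand_grid(regulator = ranking$regulators,
                              target = ranking$genes)
  edges <- dplyr::filter(edges, .data$regulator != .data$target)
  edges$weight <- w[cbind(edges$regulator, edges$target)]
  dplyr::arrange(edges, dplyr::desc(.data$weight), .data$regulator, .data$target)
}

#' @export
print.link_ranking <- function(x, ...) {
  cat("Link ranking (", x$method, "): ", length(x$genes), " genes, ",
      length(x$regulators), " candidate regulators\n", sep = "")
  print(utils::head(rank_edges(x), 10))
  invisible(x)
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("Gene network fit (", x$method, "): ", length(x$genes), " genes, ",
      x$config$n_trees, " trees per gene, seed ", x$config$seed, "\n", sep = "")
  print(utils::head(rank_edges(x$ranking), 10))
  invisible(x)
}
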