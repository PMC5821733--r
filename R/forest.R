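#' Random forest settings for per-gene transcription models
#'
#' Settings for the tree ensembles that learn each gene's transcription
#' function. Defaults follow common practice for this family of methods:
#' ensembles of `n_trees = 1000` trees, with the number of variables
#' screened at each split (`k`) equal to the number of candidate
#' regulators, bootstrap resampling, and trees grown to purity.
#'
#' @param n_trees Number of trees per ensemble.
#' @param k Number of input variables sampled at each split node, or the
#'   token `"all"` for the full candidate set.
#' @param bootstrap Draw a bootstrap sample per tree (and record the
#'   out-of-bag rows)? Disabling trains every tree on the full sample.
#' @param min_samples_split Minimum node size eligible for splitting;
#'   the default of 2 grows trees to purity.
#' @param seed Integer seed controlling bootstrap draws and per-node
#'   feature subsampling; identical settings, data and seed give
#'   bit-identical forests.
#'
#' @return A `forest_config` object (a named list).
#' @export
forest_config <- function(n_trees = 1000L, k = "all", bootstrap = TRUE,
                          min_samples_split = 2L, seed = 42L) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1L) stop("`n_trees` must be a positive integer")
  if (!identical(k, "all")) {
    k <- as.integer(k)
    if (is.na(k) || k < 1L) stop("`k` must be a positive integer or \"all\"")
  }
  min_samples_split <- as.integer(min_samples_split)
  if (is.na(min_samples_split) || min_samples_split < 2L) {
    stop("`min_samples_split` must be an integer >= 2")
  }
  structure(
    list(n_trees = n_trees, k = k, bootstrap = isTRUE(bootstrap),
         min_samples_split = min_samples_split, seed = as.integer(seed)),
    class = "forest_config"
  )
}

#' Train a regression random forest with impurity-based importances
#'
#' Fits an ensemble of regression trees by recursive variance-reduction
#' splitting. At each node the split maximizing
#' \eqn{I(N) = \#S\,Var(S) - \#S_t\,Var(S_t) - \#S_f\,Var(S_f)}
#' (population variance, absolute sample counts) is chosen among `k`
#' randomly screened inputs; the chosen split's \eqn{I(N)} is credited to
#' its input variable. Per-tree importances, per-tree bootstrap
#' membership and the tree structures are all retained, which is what
#' the network-ranking, out-of-bag scoring and tree-stability
#' diagnostics downstream consume.
#'
#' @param x Numeric input matrix (rows = samples, columns = input genes;
#'   column names required).
#' @param y Numeric response vector, one value per row of `x`.
#' @param config A [forest_config()].
#'
#' @return A `grn_forest` object with elements `trees`, `tree_importance`
#'   (inputs x trees matrix of summed per-tree importances), `inbag`
#'   (samples x trees bootstrap counts), `input_genes`, `n`, and the
#'   training data (`x`, `y`) used for out-of-bag prediction.
#' @seealso [importance()], [predict.grn_forest()], [predict_oob()]
#' @export
grn_forest <- function(x, y, config = forest_config()) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (is.null(colnames(x))) stop("`x` must have column names (input genes)")
  if (nrow(x) < 2L) stop("at least 2 samples are required to train a forest")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  k <- if (identical(config$k, "all")) ncol(x) else min(config$k, ncol(x))
  # split-score ties are resolved toward the gene earliest in (C-locale)
  # name order: deterministic, and invariant to column order and to
  # positive rescaling of the targets
  tie_rank <- match(colnames(x), sort(colnames(x), method = "radix"))
  fit <- .rf_train(x, y, tie_rank, config$n_trees, k, config$bootstrap,
                   config$min_samples_split, as.double(config$seed))
  rownames(fit$tree_importance) <- colnames(x)
  structure(
    list(trees = fit$trees,
         tree_importance = fit$tree_importance,
         inbag = fit$inbag,
         input_genes = colnames(x),
         n = nrow(x),
         x = x, y = y,
         config = config),
    class = "grn_forest"
  )
}

#' Raw variable-importance scores of a trained forest
#'
#' The Mean Decrease Impurity importance of each input: the per-tree sum
#' of the variance reductions \eqn{I(N)} over the nodes split on that
#' input, averaged over trees. For a single fully grown tree trained
#' without bootstrap or feature subsampling the importances sum exactly
#' to \eqn{N_S\,Var(S)}, the total output variation of its sample.
#'
#' @param model A [grn_forest()] fit.
#' @return Named numeric vector of non-negative importances, one per
#'   input gene.
#' @export
importance <- function(model) {
  stopifnot(inherits(model, "grn_forest"))
  rowMeans(model$tree_importance)
}

#' Predict from a trained gene forest
#'
#' @param object A [grn_forest()] fit.
#' @param newdata Numeric matrix with the model's input genes as columns
#'   (matched by name when named), or a named numeric vector for a
#'   single state.
#' @param ... Unused.
#' @return Numeric vector of ensemble-mean predictions.
#' @export
predict.grn_forest <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$input_genes, colnames(newdata))
    if (length(missing) > 0L) {
      stop("`newdata` lacks input genes: ", paste(missing, collapse = ", "))
    }
    newdata <- newdata[, object$input_genes, drop = FALSE]
  } else if (ncol(newdata) != length(object$input_genes)) {
    stop("`newdata` has ", ncol(newdata), " columns; model expects ",
         length(object$input_genes))
  }
  .rf_predict(object$trees, newdata)
}

#' Out-of-bag predictions on the training rows
#'
#' For each training row, the mean prediction over the trees whose
#' bootstrap sample left that row out. Rows in-bag for every tree are
#' `NA`; with many trees this is vanishingly rare.
#'
#' @param model A [grn_forest()] fit trained with `bootstrap = TRUE`.
#' @return Numeric vector of length `model$n`, `NA` where no tree left
#'   the row out.
#' @export
predict_oob <- function(model) {
  stopifnot(inherits(model, "grn_forest"))
  if (!model$config$bootstrap) {
    stop("out-of-bag predictions require a forest trained with bootstrap = TRUE")
  }
  .rf_predict_oob(model$trees, model$inbag, model$x)
}

#' @export
print.grn_forest <- function(x, ...) {
  cat("Regression random forest for target gene models\n")
  cat("  inputs: ", length(x$input_genes), " genes; samples: ", x$n,
      "; trees: ", x$config$n_trees, "\n", sep = "")
  invisible(x)
}
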