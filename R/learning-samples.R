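#' A single time-series expression experiment
#'
#' One experiment's trajectory: expression of `p` genes sampled at `N`
#' strictly increasing time points (arbitrary time and expression
#' units). At least two points are required, since every regression
#' sample is built from a consecutive pair of time points.
#'
#' @param times Numeric vector of sampling times, strictly increasing.
#' @param values Numeric matrix, rows = time points, columns = genes
#'   (column names required).
#' @param label Experiment identifier.
#' @return An `expression_series` object.
#' @export
expression_series <- function(times, values, label = "series") {
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (is.null(colnames(values))) stop("`values` must have gene names as columns")
  if (anyDuplicated(colnames(values))) stop("duplicate gene names in `values`")
  if (length(times) != nrow(values)) stop("length(times) must equal nrow(values)")
  if (length(times) < 2L) stop("a time series needs at least 2 time points")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (anyNA(values)) stop("missing expression values are not supported")
  structure(list(times = times, values = values, label = as.character(label)),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat("Expression time series \"", x$label, "\": ", length(x$times),
      " time points x ", ncol(x$values), " genes (t = ", x$times[1], " .. ",
      x$times[length(x$times)], ")\n", sep = "")
  invisible(x)
}

as_series_list <- function(series) {
  if (inherits(series, "expression_series")) series <- list(series)
  if (!is.list(series) || !all(vapply(series, inherits, logical(1), "expression_series"))) {
    stop("`series` must be an expression_series or a list of them")
  }
  genes <- colnames(series[[1]]$values)
  for (s in series[-1]) {
    if (!identical(colnames(s$values), genes)) {
      stop("all series must share the same genes in the same order")
    }
  }
  series
}

series_genes <- function(series) colnames(as_series_list(series)[[1]]$values)

resolve_inputs <- function(genes, target_gene, regulators, include_target) {
  if (is.null(regulators)) regulators <- genes
  unknown <- setdiff(regulators, genes)
  if (length(unknown) > 0L) {
    stop("unknown candidate regulators: ", paste(unknown, collapse = ", "))
  }
  if (length(regulators) == 0L) stop("candidate regulator set is empty")
  inputs <- if (include_target) union(regulators, target_gene)
            else setdiff(regulators, target_gene)
  genes[genes %in% inputs] # preserve canonical gene order
}

new_learning_sample <- function(inputs, targets, target_gene, origin,
                                x_prev, dt, x_next) {
  structure(
    list(inputs = inputs, targets = targets, target_gene = target_gene,
         input_genes = colnames(inputs), origin = origin,
         x_prev = x_prev, dt = dt, x_next = x_next),
    class = "learning_sample"
  )
}

#' Build the time-series learning sample of one target gene
#'
#' The first-order decay model
#' \eqn{dx_j/dt = -\alpha_j x_j(t) + f_j(x(t))} is discretized by a
#' forward finite difference over each pair of consecutive time points,
#' giving one regression case per pair: input \eqn{x(t_k)} (restricted
#' to the candidate regulators plus the target gene itself) and output
#' \deqn{y_k = \frac{x_j(t_{k+1}) - x_j(t_k)}{t_{k+1} - t_k} + \alpha_j x_j(t_k).}
#' Multiple experiments contribute the union of their per-series
#' samples; no case ever spans two different series.
#'
#' @param series An `expression_series` or list of them (shared genes).
#' @param target_gene Name of the target gene \eqn{j}.
#' @param alpha Decay rate \eqn{\alpha_j > 0} (inverse time units).
#' @param regulators Optional candidate regulator names; default all
#'   genes. The target's own expression is always included as an input
#'   (its importance is discarded later, at ranking time).
#' @return A `learning_sample` with \eqn{\sum_s (N_s - 1)} rows, each
#'   tagged `origin = "time_series"` and carrying the bookkeeping
#'   (`x_prev`, `dt`, `x_next`) needed to reconstruct predicted
#'   expression levels from predicted regression outputs.
#' @export
build_ts_learning_sample <- function(series, target_gene, alpha,
                                     regulators = NULL) {
  series <- as_series_list(series)
  genes <- series_genes(series)
  if (!target_gene %in% genes) stop("unknown target gene: ", target_gene)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive decay rate")
  }
  inputs_genes <- resolve_inputs(genes, target_gene, regulators,
                                 include_target = TRUE)
  rows_in <- list(); y <- numeric(0); xp <- numeric(0); dts <- numeric(0)
  xn <- numeric(0)
  for (s in series) {
    n <- length(s$times)
    dt <- diff(s$times)
    if (any(dt == 0)) stop("zero time interval in series \"", s$label, "\"")
    xj <- s$values[, target_gene]
    k <- seq_len(n - 1L)
    rows_in[[length(rows_in) + 1L]] <- s$values[k, inputs_genes, drop = FALSE]
    y <- c(y, (xj[k + 1L] - xj[k]) / dt + alpha * xj[k])
    xp <- c(xp, xj[k]); dts <- c(dts, dt); xn <- c(xn, xj[k + 1L])
  }
  inputs <- do.call(rbind, rows_in)
  rownames(inputs) <- NULL
  new_learning_sample(inputs, y, target_gene,
                      origin = rep("time_series", length(y)),
                      x_prev = xp, dt = dts, x_next = xn)
}

#' Build the steady-state learning sample of one target gene
#'
#' At equilibrium the decay model reduces to
#' \eqn{\alpha_j x_j = f_j(x)}, so each steady-state condition
#' contributes one case with input \eqn{x(e_k)} and output
#' \eqn{\alpha_j x_j(e_k)}.
#'
#' @param ss Steady-state matrix, rows = conditions, columns = genes.
#' @inheritParams build_ts_learning_sample
#' @return A `learning_sample` with one row per condition, tagged
#'   `origin = "steady_state"`.
#' @export
build_ss_learning_sample <- function(ss, target_gene, alpha,
                                     regulators = NULL) {
  ss <- as.matrix(ss)
  if (is.null(colnames(ss))) stop("`ss` must have gene names as columns")
  genes <- colnames(ss)
  if (!target_gene %in% genes) stop("unknown target gene: ", target_gene)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive decay rate")
  }
  if (nrow(ss) < 1L) stop("steady-state matrix has no conditions")
  inputs_genes <- resolve_inputs(genes, target_gene, regulators,
                                 include_target = TRUE)
  inputs <- ss[, inputs_genes, drop = FALSE]
  rownames(inputs) <- NULL
  m <- nrow(ss)
  new_learning_sample(inputs, alpha * ss[, target_gene], target_gene,
                      origin = rep("steady_state", m),
                      x_prev = rep(NA_real_, m), dt = rep(NA_real_, m),
                      x_next = rep(NA_real_, m))
}

#' Merge time-series and steady-state learning samples
#'
#' Row-wise union of two learning samples for the same target gene and
#' input set. Per-row origin tags are preserved so that downstream
#' out-of-bag scoring can restrict itself to time-series rows.
#'
#' @param ls_ts,ls_ss `learning_sample` objects with identical
#'   `input_genes` and `target_gene` (either may be `NULL`).
#' @return The concatenated `learning_sample`.
#' @export
merge_learning_samples <- function(ls_ts, ls_ss) {
  if (is.null(ls_ss)) return(ls_ts)
  if (is.null(ls_ts)) return(ls_ss)
  stopifnot(inherits(ls_ts, "learning_sample"), inherits(ls_ss, "learning_sample"))
  if (!identical(ls_ts$input_genes, ls_ss$input_genes)) {
    stop("learning samples have different input gene lists")
  }
  if (!identical(ls_ts$target_gene, ls_ss$target_gene)) {
    stop("learning samples target different genes")
  }
  new_learning_sample(rbind(ls_ts$inputs, ls_ss$inputs),
                      c(ls_ts$targets, ls_ss$targets),
                      ls_ts$target_gene,
                      origin = c(ls_ts$origin, ls_ss$origin),
                      x_prev = c(ls_ts$x_prev, ls_ss$x_prev),
                      dt = c(ls_ts$dt, ls_ss$dt),
                      x_next = c(ls_ts$x_next, ls_ss$x_next))
}

#' @export
print.learning_sample <- function(x, ...) {
  cat("Learning sample for gene ", x$target_gene, ": ", length(x$targets),
      " rows (", sum(x$origin == "time_series"), " time-series, ",
      sum(x$origin == "steady_state"), " steady-state), ",
      length(x$input_genes), " inputs\n", sep = "")
  invisible(x)
}

#' Data-derived mRNA decay rates
#'
#' Estimates each gene's first-order decay rate from its observed
#' expression by assuming an exponential decay \eqn{e^{-\alpha_j t}}
#' between the gene's highest and lowest values within a series:
#' \deqn{\alpha_{j,s} = \frac{\ln(x_{max} / x_{min})}{|t(x_{min}) - t(x_{max})|},}
#' aggregated over series by the maximum (the fastest decay observed).
#' Minima are floored at \eqn{10^{-6} x_{max}} so zero measurements do
#' not produce infinite rates; genes that never vary inherit the median
#' rate of the genes that do.
#'
#' @param series An `expression_series` or list of them.
#' @return A tibble with columns `gene`, `alpha`, `source`
#'   (`"data_derived"`, or `"median_fill"` for constant genes).
#' @export
estimate_decay_rates <- function(series) {
  series <- as_series_list(series)
  genes <- series_genes(series)
  per_gene <- vapply(genes, function(g) {
    rates <- vapply(series, function(s) {
      xj <- s$values[, g]
      i_max <- which.max(xj); i_min <- which.min(xj)
      x_max <- xj[i_max]; x_min <- xj[i_min]
      if (x_max <= x_min || x_max <= 0) return(NA_real_)
      x_min <- max(x_min, 1e-6 * x_max)
      log(x_max / x_min) / abs(s$times[i_min] - s$times[i_max])
    }, numeric(1))
    if (all(is.na(rates))) NA_real_ else max(rates, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(per_gene))) {
    stop("no gene varies over time; decay rates cannot be estimated ",
         "from these data -- supply rates explicitly")
  }
  filled <- unname(is.na(per_gene))
  per_gene[filled] <- stats::median(per_gene[!filled])
  tibble::tibble(gene = genes, alpha = unname(per_gene),
                 source = ifelse(filled, "median_fill", "data_derived"))
}

#' Subsample the time points of a series
#'
#' Utility for studying how inference degrades when the sampling budget
#' is halved: keep either the first half of the time points or every
#' other time point over the whole series.
#'
#' @param series An `expression_series` with at least 4 points.
#' @param mode `"first_half"` (points `1..ceiling(N/2)`) or
#'   `"every_other"` (points `1, 3, 5, ...`).
#' @return The subsampled `expression_series`.
#' @export
subset_time_points <- function(series, mode = c("first_half", "every_other")) {
  stopifnot(inherits(series, "expression_series"))
  mode <- match.arg(mode)
  n <- length(series$times)
  if (n < 4L) stop("subsampling needs at least 4 time points")
  keep <- switch(mode,
                 first_half = seq_len(ceiling(n / 2)),
                 every_other = seq(1L, n, by = 2L))
  expression_series(series$times[keep], series$values[keep, , drop = FALSE],
                    label = paste0(series$label, " [", mode, "]"))
}
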