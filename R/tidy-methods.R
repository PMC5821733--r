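#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted network into its ranked edge list
#'
#' @param x A `grn_fit`.
#' @param ... Unused.
#' @return The [rank_edges()] tibble (`regulator`, `target`, `weight`).
#' @export
tidy.grn_fit <- function(x, ...) rank_edges(x$ranking)

#' @rdname tidy.grn_fit
#' @export
tidy.link_ranking <- function(x, ...) rank_edges(x)

#' Tidy a precision-recall result into its curve points
#'
#' @param x A `pr_result`.
#' @param ... Unused.
#' @return Tibble with `rank`, `recall`, `precision`.
#' @export
tidy.pr_result <- function(x, ...) x$curve

#' One-row summary of a fitted network
#'
#' @param x A `grn_fit`.
#' @param ... Unused.
#' @return One-row tibble: method, dimensions, forest settings, seed.
#' @export
glance.grn_fit <- function(x, ...) {
  n_rows <- length(x$models[[1]]$y)
  tibble::tibble(method = x$method,
                 n_genes = length(x$genes),
                 n_regulators = length(x$regulators),
                 n_samples = n_rows,
                 n_trees = x$config$n_trees,
                 k = if (identical(x$config$k, "all")) NA_integer_
                     else x$config$k,
                 seed = x$config$seed)
}

#' @rdname glance.grn_fit
#' @export
glance.pr_result <- function(x, ...) {
  tibble::tibble(aupr = x$aupr, positives = x$positives,
                 eligible_pairs = x$eligible_pairs,
                 random_aupr = x$positives / x$eligible_pairs)
}

#' Plot a precision-recall curve
#'
#' @param object A [pr_curve()] result.
#' @param ... Unused.
#' @return A ggplot: precision vs recall, with the random-ranking
#'   expectation as a dashed horizontal line.
#' @export
autoplot.pr_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall,
                                             y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = object$positives / object$eligible_pairs,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("AUPR = %.3f", object$aupr)) +
    ggplot2::theme_minimal()
}

#' Plot a link ranking as a regulator-by-target heat map
#'
#' @param object A `link_ranking`.
#' @param ... Unused.
#' @return A ggplot tile map of the normalized weights.
#' @export
autoplot.link_ranking <- function(object, ...) {
  df <- tidyr::expand_grid(regulator = object$regulators,
                           target = object$genes)
  df$weight <- object$weights[cbind(df$regulator, df$target)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$regulator,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Target gene", y = "Regulator",
                  fill = "Weight", title = object$method) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a simulated expression trajectory
#'
#' @param object A `grn_simulation` from [simulate_to_steady_state()].
#' @param ... Unused.
#' @return A ggplot of expression vs time, one line per gene.
#' @export
autoplot.grn_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, -"time",
                              names_to = "gene", values_to = "expression")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$expression,
                                     colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time", y = "Expression", colour = "Gene") +
    ggplot2::theme_minimal()
}
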