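#' Sweep the decay-rate parameter and report tuning criteria
#'
#' Refits the dynamical model with every candidate decay setting and
#' reports, per setting: the out-of-bag prediction score, the
#' tree-stability score, and — when a gold standard is supplied — the
#' AUPR and top-k overlap. Each row of the result is one candidate:
#' every value of `alpha_grid` applied uniformly to all genes, plus one
#' distinguished row per named entry of `alpha_named` (e.g. data-derived
#' or experimentally measured per-gene rates).
#'
#' @param series An [expression_series()] or list of them.
#' @param ss Optional steady-state matrix.
#' @param gold Optional gold-standard edge tibble.
#' @param alpha_grid Numeric vector of uniform decay-rate values.
#' @param alpha_named Optional named list of per-gene rate vectors (or
#'   decay tibbles) reported as labelled rows.
#' @param regulators Optional candidate regulators.
#' @param config A [forest_config()].
#' @param top_k Top-set size for the overlap criterion.
#' @param top_m Per-tree top-set size for the stability criterion.
#' @return A tibble with one row per candidate: `alpha` (label),
#'   `oob_score`, `stability`, and `aupr`, `topk` when `gold` is given.
#' @export
tune_decay <- function(series, ss = NULL, gold = NULL,
                       alpha_grid = 10^seq(-2, 1, length.out = 7),
                       alpha_named = NULL, regulators = NULL,
                       config = forest_config(), top_k = 500L, top_m = 5L) {
  candidates <- c(
    stats::setNames(as.list(alpha_grid), format(alpha_grid, digits = 4,
                                                trim = TRUE)),
    alpha_named
  )
  rows <- purrr::imap(candidates, function(decay, label) {
    fit <- dyngenie3(series, ss = ss, decay = decay,
                     regulators = regulators, config = config)
    row <- tibble::tibble(alpha = label,
                          oob_score = oob_prediction_score(fit),
                          stability = stability_score(fit, top_m = top_m))
    if (!is.null(gold)) {
      pr <- pr_curve(fit, gold)
      row$aupr <- pr$aupr
      row$topk <- topk_overlap(fit, gold, k = top_k)
    }
    row
  })
  dplyr::bind_rows(rows)
}
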