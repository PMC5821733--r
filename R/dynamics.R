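# Fitted per-gene forests used generatively: the learned ODE
# dx_j/dt = -alpha_j x_j + f_hat_j(x) is integrated by explicit Euler,
# which is exactly the finite-difference scheme the models were trained
# under when the step equals the data's sampling interval.

check_dyn_fit <- function(fit) {
  if (!inherits(fit, "grn_fit") || is.null(fit$alpha)) {
    stop("trajectory simulation needs a dynamical fit (from dyngenie3())")
  }
}

transcription_rates <- function(fit, x) {
  vapply(fit$genes, function(j) {
    predict(fit$models[[j]], x)[1]
  }, numeric(1))
}

#' One Euler step of the learned expression dynamics
#'
#' Advances the state by
#' \eqn{x_j(t+\Delta t) = x_j(t) + \Delta t\,(\hat f_j(x(t)) - \alpha_j x_j(t))}
#' for every unclamped gene; clamped genes are copied unchanged and
#' negative results are floored at 0 (expression is non-negative and the
#' forests cannot extrapolate below the training range).
#'
#' @param fit A dynamical `grn_fit` from [dyngenie3()].
#' @param x Named state vector covering all genes.
#' @param dt Step size (time units).
#' @param clamped Character vector of genes held fixed.
#' @return The next state, same names as `x`.
#' @export
step_expression <- function(fit, x, dt, clamped = character(0)) {
  check_dyn_fit(fit)
  stopifnot(dt > 0)
  x <- x[fit$genes]
  if (anyNA(x)) stop("`x` must cover every gene of the fit")
  f <- transcription_rates(fit, x)
  x_new <- pmax(x + dt * (f - fit$alpha * x), 0)
  x_new[clamped] <- x[clamped]
  x_new
}

#' Simulate the learned dynamics to a steady state
#'
#' Iterates [step_expression()] from `x0` until the largest relative
#' per-step change over unclamped genes drops below `tol`, or
#' `max_steps` is reached.
#'
#' @param fit A dynamical `grn_fit` from [dyngenie3()].
#' @param x0 Named initial state.
#' @param dt Step size; defaults to the median sampling interval of the
#'   training series (the scheme the models were trained under).
#' @param max_steps Maximum number of steps.
#' @param tol Relative sup-norm change per step declaring convergence.
#' @param clamped Genes held at their `x0` value throughout.
#' @return A `grn_simulation`: list with `trajectory` (tibble: `time`
#'   column then one column per gene), `steady_state` (named vector),
#'   `converged` (flag) and `steps`.
#' @export
simulate_to_steady_state <- function(fit, x0, dt = NULL, max_steps = 1000L,
                                     tol = 1e-4, clamped = character(0)) {
  check_dyn_fit(fit)
  unknown <- setdiff(clamped, fit$genes)
  if (length(unknown) > 0L) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (is.null(dt)) {
    dts <- unlist(lapply(fit$models, function(m) m$learning_sample$dt))
    dt <- stats::median(dts, na.rm = TRUE)
  }
  x <- x0[fit$genes]
  if (anyNA(x)) stop("`x0` must cover every gene of the fit")
  free <- setdiff(fit$genes, clamped)
  traj <- matrix(NA_real_, nrow = max_steps + 1L, ncol = length(fit$genes),
                 dimnames = list(NULL, fit$genes))
  traj[1L, ] <- x
  converged <- FALSE
  steps <- 0L
  for (s in seq_len(max_steps)) {
    x_new <- step_expression(fit, x, dt, clamped)
    if (any(!is.finite(x_new))) {
      bad <- fit$genes[!is.finite(x_new)][1]
      stop("non-finite expression for gene ", bad, " at step ", s)
    }
    traj[s + 1L, ] <- x_new
    steps <- s
    rel <- abs(x_new[free] - x[free]) / pmax(abs(x[free]), 1e-12)
    x <- x_new
    if (length(free) == 0L || max(rel) < tol) {
      converged <- TRUE
      break
    }
  }
  traj <- traj[seq_len(steps + 1L), , drop = FALSE]
  trajectory <- dplyr::bind_cols(
    tibble::tibble(time = dt * (seq_len(nrow(traj)) - 1L)),
    tibble::as_tibble(traj))
  structure(list(trajectory = trajectory, steady_state = x,
                 converged = converged, steps = steps, dt = dt,
                 clamped = clamped),
            class = "grn_simulation")
}

#' @export
print.grn_simulation <- function(x, ...) {
  cat("Simulated trajectory: ", x$steps, " steps of dt = ", x$dt,
      if (x$converged) " (converged)" else " (max steps reached)", "\n", sep = "")
  invisible(x)
}

#' Predict the steady-state response to a double knockout
#'
#' Starts from the wild-type expression levels with the two deleted
#' genes set to zero, clamps the deleted genes at zero throughout (a
#' deleted gene cannot be re-expressed), and simulates the learned
#' dynamics to a steady state. The conventional baseline — using the
#' initial levels at t = 0 as the prediction — is returned alongside.
#'
#' @param fit A dynamical `grn_fit` from [dyngenie3()].
#' @param wild_type Named wild-type expression vector.
#' @param deleted Character vector of exactly two distinct gene names.
#' @inheritParams simulate_to_steady_state
#' @return List with `prediction` (steady state; deleted genes exactly
#'   0), `baseline` (the initial levels), `simulation` (the full
#'   `grn_simulation`).
#' @export
predict_double_knockout <- function(fit, wild_type, deleted, dt = NULL,
                                    max_steps = 1000L, tol = 1e-4) {
  check_dyn_fit(fit)
  deleted <- unique(as.character(deleted))
  if (length(deleted) != 2L) stop("`deleted` must name two distinct genes")
  unknown <- setdiff(deleted, fit$genes)
  if (length(unknown) > 0L) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  x0 <- wild_type[fit$genes]
  if (anyNA(x0)) stop("`wild_type` must cover every gene of the fit")
  x0[deleted] <- 0
  sim <- simulate_to_steady_state(fit, x0, dt = dt, max_steps = max_steps,
                                  tol = tol, clamped = deleted)
  prediction <- sim$steady_state
  prediction[deleted] <- 0
  list(prediction = prediction, baseline = x0, simulation = sim)
}

#' Out-of-bag prediction score of a dynamical fit
#'
#' An unbiased estimate of how well the fitted models predict unseen
#' expression levels, without refitting: for every time-series training
#' row left out of at least one tree's bootstrap, the out-of-bag
#' regression prediction \eqn{\hat y} is mapped back to an expression
#' prediction
#' \eqn{\hat x_j(t_{k+1}) = x_j(t_k) + \Delta t (\hat y - \alpha_j x_j(t_k))},
#' correlated with the true \eqn{x_j(t_{k+1})} per gene (Pearson), and
#' averaged over the genes with at least 3 scored rows and non-degenerate
#' variance. Used to compare candidate decay-rate settings.
#'
#' @param fit A dynamical `grn_fit` from [dyngenie3()] trained with
#'   bootstrap.
#' @return A single correlation in \eqn{[-1, 1]}.
#' @export
oob_prediction_score <- function(fit) {
  check_dyn_fit(fit)
  scores <- vapply(fit$genes, function(j) {
    model <- fit$models[[j]]
    ls <- model$learning_sample
    ts <- which(ls$origin == "time_series")
    if (length(ts) == 0L) return(NA_real_)
    y_oob <- predict_oob(model)[ts]
    ok <- !is.na(y_oob)
    if (sum(ok) == 0L) return(NA_real_)
    x_hat <- ls$x_prev[ts][ok] +
      ls$dt[ts][ok] * (y_oob[ok] - model$alpha * ls$x_prev[ts][ok])
    x_true <- ls$x_next[ts][ok]
    if (length(x_true) < 3L || stats::sd(x_true) == 0 || stats::sd(x_hat) == 0) {
      return(NA_real_)
    }
    stats::cor(x_hat, x_true)
  }, numeric(1))
  if (all(is.na(scores))) {
    stop("no out-of-bag predictions available; grow more trees or enable bootstrap")
  }
  mean(scores, na.rm = TRUE)
}

#' Pearson correlation between predicted and true expression levels
#'
#' Plain product-moment correlation with the degenerate cases made
#' explicit: fewer than 3 pairs or zero variance in either vector give
#' `NA` (the correlation is undefined, not zero).
#'
#' @param predicted,true Equal-length numeric vectors.
#' @return Pearson r, or `NA` when undefined.
#' @export
prediction_correlation <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("vectors differ in length")
  if (length(predicted) < 3L) return(NA_real_)
  if (stats::sd(predicted) == 0 || stats::sd(true) == 0) return(NA_real_)
  stats::cor(predicted, true)
}
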