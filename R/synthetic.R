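# DREAM4-like benchmark generator. The generating dynamics are
# deliberately NOT the learner's model class: transcription is a
# saturating (Hill-type) sum of regulator effects, so recovery tests
# probe the method under model mismatch, as any in-silico benchmark
# does.

#' Sample a random ground-truth regulatory network
#'
#' Directed random graph without self-loops. Edge strengths are
#' steady-state gains uniform on \eqn{\pm[0.5, 2]} (sign =
#' activation/repression): the transcription rate of gene \eqn{j} is
#' \eqn{f_j(x) = \alpha_j (b_j + \sum_i s_{ij} H(x_i))} with a Hill
#' saturation \eqn{H}, so the decay rate \eqn{\alpha_j} sets only the
#' kinetic timescale and expression levels stay of order 1. Decay rates
#' are uniform on \eqn{[0.005, 0.02]} inverse time units — half-lives
#' of 0.7–2.8 sampling intervals under the default 50-time-unit
#' sampling, so perturbation responses and the relaxation back to the
#' resting state span several sampled points, as in the benchmark
#' datasets this generator emulates.
#'
#' @param p Number of genes (>= 2).
#' @param avg_degree Average number of regulators per gene; the edge
#'   count is `round(avg_degree * p)`.
#' @param strength_range Range of absolute edge gains; e.g.
#'   `c(1.5, 2)` for uniformly strong regulation.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A `synthetic_network`: list with `genes`, `edges` (tibble
#'   `regulator`, `target`, `strength`), `alpha`, `basal`, `hill_k`.
#' @export
sample_network <- function(p, avg_degree = 1.5, strength_range = c(0.5, 2),
                           seed = 42L) {
  if (p < 2L) stop("a network needs at least 2 genes")
  n_edges <- round(avg_degree * p)
  if (n_edges > p * (p - 1L)) {
    stop("requested density exceeds the ", p * (p - 1L),
         " possible directed edges")
  }
  withr::with_seed(seed, {
    genes <- paste0("G", seq_len(p))
    # off-diagonal cells of the p x p adjacency, sampled without replacement
    cells <- sample.int(p * (p - 1L), n_edges)
    regulator <- (cells - 1L) %% p + 1L
    offset <- (cells - 1L) %/% p + 1L
    target <- (regulator + offset - 1L) %% p + 1L
    strength <- stats::runif(n_edges, strength_range[1], strength_range[2]) *
      sample(c(-1, 1), n_edges, replace = TRUE)
    structure(
      list(genes = genes,
           edges = tibble::tibble(regulator = genes[regulator],
                                  target = genes[target],
                                  strength = strength),
           alpha = stats::setNames(stats::runif(p, 0.005, 0.02), genes),
           basal = stats::setNames(stats::runif(p, 0.2, 1), genes),
           hill_k = 1),
      class = "synthetic_network"
    )
  })
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat("Synthetic regulatory network: ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# Signed strength matrix (regulator x target) of a network.
net_strength_matrix <- function(net) {
  w <- matrix(0, length(net$genes), length(net$genes),
              dimnames = list(net$genes, net$genes))
  if (nrow(net$edges) > 0L) {
    w[cbind(net$edges$regulator, net$edges$target)] <- net$edges$strength
  }
  w
}

# Transcription rate of every gene: basal + signed Hill-saturated
# regulator effects + optional additive perturbation input, floored at 0.
net_transcription <- function(net, x, perturb = NULL) {
  if (is.null(net$w)) net$w <- net_strength_matrix(net)
  h <- x^2 / (x^2 + net$hill_k^2)
  gain <- net$basal + drop(h %*% net$w)
  if (!is.null(perturb)) gain <- gain + perturb
  pmax(net$alpha * gain, 0)
}

net_integrate <- function(net, x0, t_span, inner_dt, perturb = NULL,
                          clamped = character(0), record_at = NULL) {
  if (is.null(net$w)) net$w <- net_strength_matrix(net)
  x <- x0
  t <- 0
  recorded <- if (is.null(record_at)) NULL else
    matrix(NA_real_, length(record_at), length(x0),
           dimnames = list(NULL, names(x0)))
  ri <- 1L
  record <- function(t) {
    while (ri <= length(record_at) && record_at[ri] <= t + 1e-9) {
      recorded[ri, ] <<- x
      ri <<- ri + 1L
    }
  }
  record(t)
  n_steps <- ceiling(t_span / inner_dt)
  for (s in seq_len(n_steps)) {
    f <- net_transcription(net, x, perturb)
    x_new <- pmax(x + inner_dt * (f - net$alpha * x), 0)
    x_new[clamped] <- x[clamped]
    if (any(!is.finite(x_new))) {
      stop("synthetic dynamics diverged (non-finite expression); ",
           "choose a different seed")
    }
    x <- x_new
    t <- t + inner_dt
    record(t)
  }
  list(x = x, recorded = recorded)
}

net_steady_state <- function(net, x0, inner_dt, perturb = NULL,
                             clamped = character(0), t_span = 2000,
                             tol = 1e-9) {
  if (is.null(net$w)) net$w <- net_strength_matrix(net)
  x <- x0
  for (chunk in 1:20) {
    res <- net_integrate(net, x, t_span, inner_dt, perturb, clamped)
    f <- net_transcription(net, res$x, perturb)
    resid <- abs(f - net$alpha * res$x)
    resid[clamped] <- 0
    x <- res$x
    if (max(resid) < tol) break
  }
  x
}

#' Simulate a DREAM4-like benchmark dataset from a ground-truth network
#'
#' Produces the full file set the inference pipeline consumes: time
#' series experiments (a random perturbation applied at t = 0 and
#' removed after `perturbation_removed_after` sampled points, after
#' which the system relaxes back to its resting state), a steady-state
#' matrix (wild type, one knockout per gene, and multifactorial
#' conditions with jittered basal rates), the systematic knockout
#' matrix with its wild-type row, the gold-standard edge list, and the
#' true decay rates. Observation noise is additive Gaussian truncated
#' at 0. Dynamics are integrated by explicit Euler with an inner step of
#' `interval / 50`.
#'
#' @param net A [sample_network()] result.
#' @param n_series Number of time series experiments.
#' @param n_points Sampled time points per series (default 21).
#' @param interval Sampling interval in time units (default 50).
#' @param noise_sd Observation noise standard deviation (default 0.02).
#' @param perturbation_removed_after Number of sampled points during
#'   which the perturbation stays applied (default 10).
#' @param n_multifactorial Number of multifactorial steady-state
#'   conditions (default 5).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return List with `series` (list of [expression_series()]), `ss`
#'   (conditions x genes matrix), `ko` (list `ko_values`, `wild_type`),
#'   `gold` (edge tibble), `alpha` (true decay rates), `network`.
#' @export
simulate_dataset <- function(net, n_series = 5L, n_points = 21L,
                             interval = 50, noise_sd = 0.02,
                             perturbation_removed_after = 10L,
                             n_multifactorial = 5L, seed = 42L) {
  stopifnot(inherits(net, "synthetic_network"))
  net$w <- net_strength_matrix(net)
  p <- length(net$genes)
  inner_dt <- interval / 50
  withr::with_seed(seed, {
    observe <- function(x) {
      if (noise_sd == 0) return(x)
      pmax(x + stats::rnorm(length(x), 0, noise_sd), 0)
    }
    wt <- net_steady_state(net, net$basal, inner_dt)

    series <- vector("list", n_series)
    times <- interval * (seq_len(n_points) - 1L)
    t_on <- interval * perturbation_removed_after
    for (s in seq_len(n_series)) {
      n_pert <- max(1L, round(p / 3))
      hit <- sample(net$genes, n_pert)
      perturb <- stats::setNames(numeric(p), net$genes)
      perturb[hit] <- stats::runif(n_pert, 0.5, 1.5) *
        sample(c(-1, 1), n_pert, replace = TRUE, prob = c(0.3, 0.7))
      # perturbation active on [0, t_on), i.e. while the first
      # `perturbation_removed_after` points are sampled
      on_times <- times[times < t_on]
      phase1 <- net_integrate(net, wt, t_on, inner_dt,
                              perturb = perturb, record_at = on_times)
      off_times <- times[times >= t_on]
      phase2_rec <- if (length(off_times) > 0L) {
        net_integrate(net, phase1$x, max(off_times) - t_on, inner_dt,
                      record_at = off_times - t_on)$recorded
      }
      vals <- rbind(phase1$recorded, phase2_rec)
      vals[] <- observe(vals)
      series[[s]] <- expression_series(times, vals,
                                       label = paste0("series_", s))
    }

    ko <- matrix(NA_real_, p, p, dimnames = list(net$genes, net$genes))
    for (g in net$genes) {
      x0 <- wt; x0[g] <- 0
      ko[g, ] <- net_steady_state(net, x0, inner_dt, clamped = g)
    }
    mf <- matrix(NA_real_, n_multifactorial, p,
                 dimnames = list(paste0("multifactorial_", seq_len(n_multifactorial)),
                                 net$genes))
    for (i in seq_len(n_multifactorial)) {
      net_i <- net
      net_i$basal <- net$basal * stats::runif(p, 0.75, 1.25)
      mf[i, ] <- net_steady_state(net_i, wt, inner_dt)
    }
    ko_obs <- ko; ko_obs[] <- observe(ko)
    for (g in net$genes) ko_obs[g, g] <- 0 # a deleted gene reads exactly 0
    wt_obs <- stats::setNames(observe(wt), net$genes)
    mf[] <- observe(mf)
    ss <- rbind(wild_type = wt_obs, ko_obs, mf)

    list(series = series, ss = ss,
         ko = list(ko_values = ko_obs, wild_type = wt_obs),
         gold = dplyr::select(net$edges, "regulator", "target"),
         alpha = net$alpha, network = net)
  })
}
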