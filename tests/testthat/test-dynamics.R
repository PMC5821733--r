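test_that("constant transcription converges to production over decay", {
  fit <- constant_fit(c(G1 = 2, G2 = 0.6), c(G1 = 0.5, G2 = 0.3))
  sim <- simulate_to_steady_state(fit, c(G1 = 0.1, G2 = 5), dt = 0.5,
                                  tol = 1e-8, max_steps = 5000)
  expect_true(sim$converged)
  expect_equal(unname(sim$steady_state), c(2 / 0.5, 0.6 / 0.3),
               tolerance = 1e-4)
  # steady-state residual bound: |f(x*) - alpha x*| small
  f_hat <- sapply(fit$genes, function(j) predict(fit$models[[j]],
                                                 sim$steady_state))
  resid <- abs(f_hat - unlist(fit$alpha) * sim$steady_state)
  expect_lt(max(resid), 1e-3)
})

test_that("a model predicting exactly the decay term is a fixed point", {
  # f_hat_j = alpha_j * x_j at the probe state: the step leaves x unchanged
  fit <- constant_fit(c(G1 = 0.8), c(G1 = 0.4))
  x_star <- c(G1 = 0.8 / 0.4)
  expect_equal(step_expression(fit, x_star, dt = 1), x_star)
})

test_that("zero transcription decays monotonically to zero", {
  fit <- constant_fit(c(G1 = 0, G2 = 0), c(G1 = 0.5, G2 = 0.2))
  sim <- simulate_to_steady_state(fit, c(G1 = 2, G2 = 1), dt = 0.5,
                                  tol = 1e-10, max_steps = 5000)
  traj <- as.matrix(sim$trajectory[, -1])
  expect_true(all(diff(traj[, "G1"]) <= 0))
  expect_true(all(diff(traj[, "G2"]) <= 0))
  expect_lt(max(sim$steady_state), 1e-3)
})

test_that("clamped genes never move and max_steps is honoured", {
  fit <- constant_fit(c(G1 = 1, G2 = 1), c(G1 = 0.5, G2 = 0.5))
  x0 <- c(G1 = 0.3, G2 = 0.3)
  for (i in 1:100) x0 <- step_expression(fit, x0, 0.5, clamped = "G1")
  expect_equal(x0[["G1"]], 0.3)

  sim1 <- simulate_to_steady_state(fit, c(G1 = 5, G2 = 5), dt = 0.5,
                                   max_steps = 1)
  expect_false(sim1$converged)
  expect_equal(sim1$steps, 1L)
  expect_lte(nrow(sim1$trajectory), 2)
})

test_that("one Euler step at a training state reproduces the finite difference", {
  s <- random_series(10, 3, seed = 21, dt = 2)
  alpha <- c(G1 = 0.2, G2 = 0.4, G3 = 0.3)
  fit <- dyngenie3(s, decay = alpha,
                   config = forest_config(n_trees = 1, bootstrap = FALSE,
                                          seed = 1))
  k <- 4
  x_next <- step_expression(fit, s$values[k, ], dt = 2)
  expect_equal(x_next, s$values[k + 1, ], tolerance = 1e-9)
})

test_that("double-knockout predictions respect deletion semantics", {
  # G1 strongly activates G2; G3, G4 have no outgoing edges
  net <- sample_network(4, avg_degree = 0, seed = 1)
  net$edges <- tibble::tibble(regulator = "G1", target = "G2", strength = 2)
  d <- simulate_dataset(net, n_series = 4, n_points = 21, noise_sd = 0,
                        seed = 2)
  fit <- dyngenie3(d$series, ss = d$ss, decay = d$alpha,
                   config = forest_config(n_trees = 100, seed = 3))
  wt <- d$ko$wild_type

  # deleting two genes with no outgoing edges leaves the rest near wild type
  res0 <- predict_double_knockout(fit, wt, c("G3", "G4"))
  expect_equal(res0$prediction[c("G3", "G4")], c(G3 = 0, G4 = 0))
  expect_equal(res0$prediction[c("G1", "G2")], wt[c("G1", "G2")],
               tolerance = 0.15)

  # deleting the strong activator of G2 drags G2 below wild type
  res1 <- predict_double_knockout(fit, wt, c("G1", "G4"))
  expect_lt(res1$prediction[["G2"]], wt[["G2"]] * 0.9)

  # baseline comparator is the t = 0 state
  expect_equal(res1$baseline[["G2"]], wt[["G2"]])
  expect_equal(res1$baseline[["G1"]], 0)
  expect_error(predict_double_knockout(fit, wt, c("G1", "G1")), "distinct")
  expect_error(predict_double_knockout(fit, wt, c("G1", "GX")), "unknown")
})

test_that("out-of-bag score separates learnable from noise dynamics", {
  # learnable: noise-free generator dynamics
  net <- sample_network(5, avg_degree = 1.5, strength_range = c(1.5, 2),
                        seed = 4)
  d <- simulate_dataset(net, n_series = 4, noise_sd = 0, seed = 4)
  fit <- dyngenie3(d$series, decay = d$alpha,
                   config = forest_config(n_trees = 300, seed = 4))
  score <- oob_prediction_score(fit)
  expect_gt(score, 0.9)
  expect_lte(abs(score), 1)

  # pure-noise targets: near-zero mean score across seeds
  null_scores <- vapply(1:20, function(seed) {
    s <- random_series(15, 3, seed = seed)
    f <- dyngenie3(s, decay = 0.5, config = forest_config(n_trees = 50,
                                                          seed = seed))
    oob_prediction_score(f)
  }, numeric(1))
  expect_lt(abs(mean(null_scores)), 0.2)
})

test_that("prediction correlation handles the degenerate cases", {
  expect_equal(prediction_correlation(1:5, 1:5), 1.0)
  expect_equal(prediction_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(prediction_correlation(c(1, 2, 3), -c(1, 2, 3)), -1.0)
  expect_true(is.na(prediction_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(prediction_correlation(1:2, 1:2)))
  expect_error(prediction_correlation(1:3, 1:4), "length")
})
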