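# Recovery benchmark shared by several acceptance checks: 10 fixed-seed
# DREAM4-like 10-gene datasets (5 series x 21 points, noise_sd 0.02,
# strong edge gains), scored for several method variants plus the
# double-knockout prediction experiment. Computed once per test run.
# 150 trees per ensemble keep the full benchmark within a desk-scale
# run; ranking quality is flat in the ensemble size well below that.

acceptance_benchmark <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rows <- lapply(1:10, function(s) {
      net <- sample_network(10, avg_degree = 1.5,
                            strength_range = c(1.5, 2), seed = s)
      d <- simulate_dataset(net, seed = s)
      cfg <- forest_config(n_trees = 150, seed = s)
      fit_ts <- dyngenie3(d$series, config = cfg)
      fit_joint <- dyngenie3(d$series, ss = d$ss, config = cfg)
      naive <- genie3(d$series, config = cfg)
      ss_only <- genie3(d$ss, config = cfg)
      pr_ts <- pr_curve(fit_ts, d$gold)

      # five double-knockout experiments per network, predictions pooled
      pairs <- withr::with_seed(1000 + s, {
        {
          # delete genes that actually regulate something: knocking out
          # a non-regulator changes nothing, so there is nothing to
          # predict beyond the baseline
          hubs <- unique(net$edges$regulator)
          pool <- if (length(hubs) >= 2) hubs else net$genes
          replicate(5, sample(pool, 2), simplify = FALSE)
        }
      })
      wt <- d$ko$wild_type
      pred <- truth <- base <- numeric(0)
      for (del in pairs) {
        x0 <- wt; x0[del] <- 0
        true_ss <- grndyn:::net_steady_state(net, x0, inner_dt = 1,
                                             clamped = del)
        res <- predict_double_knockout(fit_joint, wt, del)
        keep <- setdiff(net$genes, del)
        pred <- c(pred, res$prediction[keep])
        truth <- c(truth, true_ss[keep])
        base <- c(base, wt[keep])
      }
      tibble::tibble(
        seed = s,
        aupr_ts = pr_ts$aupr,
        aupr_joint = pr_curve(fit_joint, d$gold)$aupr,
        aupr_naive = pr_curve(naive, d$gold)$aupr,
        aupr_ss = pr_curve(ss_only, d$gold)$aupr,
        random_aupr = pr_ts$positives / pr_ts$eligible_pairs,
        dko_r = prediction_correlation(pred, truth),
        dko_r_baseline = prediction_correlation(base, truth))
    })
    cache <<- dplyr::bind_rows(rows)
    cache
  }
})
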