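test_that("empty-adjustment TMLEs reduce to the unadjusted contrasts", {
  for (seed in 1:5) {
    d <- random_crt(J = 12, seed = seed)
    for (lvl in c("cluster", "individual")) {
      es <- estimand_spec(lvl)
      u <- unadjusted_contrast(d, es)
      ct <- cluster_tmle(d, es)
      expect_equal(ct$estimate, u$estimate, tolerance = 1e-12)
      expect_equal(ct$psi1, u$psi1, tolerance = 1e-12)
      expect_equal(ct$se, u$se, tolerance = 1e-10)
    }
    # hierarchical TMLE without adjustment targets the pooled means exactly
    h <- hierarchical_tmle(d, estimand_spec("individual"))
    expect_equal(h$estimate,
                 pooled_individual_mean(d, 1) / pooled_individual_mean(d, 0),
                 tolerance = 1e-12)
    # hybrid with an intercept-only individual regression matches the
    # cluster-level TMLE with empty adjustment (same target)
    hy <- hybrid_tmle(d, estimand_spec("individual"))
    ct_i <- cluster_tmle(d, estimand_spec("individual"))
    expect_equal(hy$estimate, ct_i$estimate, tolerance = 1e-10)
  }
})

test_that("the fluctuation solves the efficient score equation", {
  # after targeting, sum_j w_j H_j(a) (Yc_j - mu*_j) = 0 for both arms;
  # the per-cluster influence-function values then sum to exactly zero.
  d <- simulate_crt(dgp_config("sim1", J = 20, seed = 13))
  fits <- list(
    cluster_tmle(d, estimand_spec("cluster"), "W1c", "W2c"),
    cluster_tmle(d, estimand_spec("individual"), c("W1c", "E1"), "E2"),
    hierarchical_tmle(d, estimand_spec("individual"), c("W1", "E1"), "W2"),
    hierarchical_tmle(d, estimand_spec("cluster"), "W1", "W2"),
    hybrid_tmle(d, estimand_spec("cluster"), c("W1", "W2"), "W1c"))
  for (f in fits) {
    expect_lt(abs(sum(f$if1)), 1e-8)
    expect_lt(abs(sum(f$if0)), 1e-8)
  }
})

test_that("ratio confidence limits are symmetric about the estimate on the log scale", {
  d <- simulate_crt(dgp_config("sim2", J = 20, seed = 23))
  for (f in list(cluster_tmle(d, estimand_spec("individual"), "W1c"),
                 hierarchical_tmle(d, estimand_spec("individual"), "W1"),
                 unadjusted_contrast(d, estimand_spec("cluster")))) {
    expect_equal(log(f$ci_lo) + log(f$ci_hi), 2 * log(f$estimate),
                 tolerance = 1e-12)
    expect_true(f$ci_lo <= f$estimate && f$estimate <= f$ci_hi)
  }
})

test_that("targets coincide for equal cluster sizes", {
  d <- random_crt(J = 10, equal_n = 20, seed = 7)
  for (fit in list(cluster_tmle, hierarchical_tmle)) {
    adj <- if (identical(fit, cluster_tmle)) "W1c" else "W1"
    f_c <- fit(d, estimand_spec("cluster"), adj)
    f_i <- fit(d, estimand_spec("individual"), adj)
    expect_equal(f_c$estimate, f_i$estimate, tolerance = 1e-12)
  }
})

test_that("hybrid and hierarchical TMLE agree closely for the same regression", {
  d <- simulate_crt(dgp_config("sim1", J = 20, seed = 29))
  es <- estimand_spec("individual")
  hy <- hybrid_tmle(d, es, outcome_adj = c("W1", "W2"))
  hi <- hierarchical_tmle(d, es, outcome_adj = c("W1", "W2"))
  expect_equal(hy$estimate, hi$estimate, tolerance = 0.02)
})

test_that("estimated propensities are truncated with a warning", {
  d <- random_crt(J = 20, seed = 41)
  # make E1 strongly (not perfectly) predictive of the arm
  d$clusters$E1 <- d$clusters$A * 2 - 1 + rnorm(20, 0, 0.4)
  expect_warning(cluster_tmle(d, estimand_spec("cluster"), ps_adj = "E1"),
                 "truncated|known 0.5")
})

test_that("continuous outcomes are rejected by the logistic fluctuation", {
  d <- random_crt(J = 8, seed = 5)
  d$individuals$Y <- d$individuals$Y + 0.1
  expect_error(cluster_tmle(d, estimand_spec()), "binary|bounded")
  expect_error(hierarchical_tmle(d, estimand_spec()), "binary")
})

test_that("keeping matched pairs pools the influence function over J/2 units", {
  d <- random_crt(J = 12, seed = 19, paired = TRUE)
  keep <- cluster_tmle(d, estimand_spec("cluster", matching = "keep"), "E1")
  brk <- cluster_tmle(d, estimand_spec("cluster", matching = "break"), "E1")
  expect_equal(keep$estimate, brk$estimate, tolerance = 1e-12)
  expect_equal(keep$df, 12 / 2 - 1)
  expect_equal(brk$df, 12 - 2)
  expect_length(keep$if1, 6)
})
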