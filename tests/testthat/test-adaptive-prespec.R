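test_that("a library with only the unadjusted candidate returns the unadjusted fit", {
  d <- random_crt(J = 12, seed = 3)
  es <- estimand_spec("cluster")
  ap <- adaptive_prespec(d, es, "cluster_tmle",
                         outcome_candidates = list(character()),
                         ps_candidates = list(character()))
  u <- unadjusted_contrast(d, es)
  expect_equal(ap$estimate, u$estimate, tolerance = 1e-12)
  expect_equal(ap$se, u$se, tolerance = 1e-10)
  expect_identical(ap$selection$outcome, character(0))
  expect_identical(ap$selection$propensity, character(0))
})

test_that("selection is deterministic given the data", {
  d <- simulate_crt(dgp_config("sim1", J = 20, seed = 8))
  es <- estimand_spec("cluster")
  a1 <- adaptive_prespec(d, es, "cluster_tmle")
  a2 <- adaptive_prespec(d, es, "cluster_tmle")
  expect_identical(a1$selection$outcome, a2$selection$outcome)
  expect_identical(a1$selection$outcome_cv, a2$selection$outcome_cv)
  expect_identical(a1$estimate, a2$estimate)
})

test_that("cross-validation avoids covariates unrelated to the outcome", {
  # in the first benchmark study W3/W4 are pure noise for the outcome:
  # the squared-IF criterion should never pick them over W1/W2
  picks <- vapply(1:25, function(r) {
    d <- simulate_crt(dgp_config("sim1", J = 20, seed = 400 + r))
    ap <- adaptive_prespec(d, estimand_spec("cluster"), "cluster_tmle")
    ap$selection$outcome_label
  }, "")
  expect_true(all(picks %in% c("W1c", "W2c")))
})

test_that("adjustment is declined when matching already captures the signal", {
  # the outcome depends on the pair-level component of E2 only; recorded E2
  # adds small within-pair measurement noise. With pairs kept, the
  # within-pair E2 variation is pure noise, so the modal choice is the
  # unadjusted candidate
  gen <- function(seed) {
    set.seed(seed)
    J <- 20
    E2p <- rep(rnorm(J / 2), each = 2)      # structural, shared by the pair
    E2 <- E2p + rnorm(J, 0, 0.05)           # recorded covariate
    pairs <- rep(seq_len(J / 2), each = 2)
    A <- integer(J)
    for (k in 1:(J / 2)) {
      m <- which(pairs == k)
      A[m] <- sample(c(1L, 0L))
    }
    rows <- lapply(1:J, function(j) {
      n <- 40
      data.frame(cluster_id = sprintf("c%02d", j),
                 pair_id = sprintf("p%02d", pairs[j]),
                 A = A[j],
                 Y = as.integer(runif(n) < plogis(-0.5 + 1.5 * E2p[j])),
                 E2 = E2[j])
    })
    crt_data(do.call(rbind, rows))
  }
  picks <- vapply(1:30, function(r) {
    d <- gen(1200 + r)
    ap <- adaptive_prespec(d, estimand_spec("cluster", matching = "keep"),
                           "cluster_tmle",
                           outcome_candidates = list(character(), "E2"),
                           ps_candidates = list(character(), "E2"))
    ap$selection$outcome_label
  }, "")
  expect_gt(mean(picks == "(unadjusted)"), 0.5)
})

test_that("ties are broken toward parsimony then lexicographic name", {
  d <- random_crt(J = 12, seed = 15)
  # duplicate covariates give exactly equal CV losses
  d$clusters$W9c <- d$clusters$W1c
  d$clusters$W8c <- d$clusters$W1c
  ap <- adaptive_prespec(d, estimand_spec("cluster"), "cluster_tmle",
                         outcome_candidates = list("W9c", "W8c", character()),
                         ps_candidates = list(character()))
  cvv <- ap$selection$outcome_cv
  expect_equal(cvv[["W8c"]], cvv[["W9c"]], tolerance = 1e-14)
  if (which.min(cvv) != 1) {  # only when duplicates beat unadjusted
    expect_identical(ap$selection$outcome, "W8c")
  }
})

test_that("adaptive selection never materially hurts efficiency", {
  ests <- list(
    estimator_spec("unadj", function(d)
      unadjusted_contrast(d, estimand_spec("cluster")), "cluster_ratio"),
    estimator_spec("ap", function(d)
      adaptive_prespec(d, estimand_spec("cluster"), "cluster_tmle"),
      "cluster_ratio"))
  s <- run_study(dgp_config("sim1", J = 20, seed = 2100), ests, R = 40)
  sig <- stats::setNames(s$sigma, s$estimator)
  expect_lt(sig[["ap"]], sig[["unadj"]] * 1.05)
})
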