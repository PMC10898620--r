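test_that("cluster aggregation reproduces the five-cluster toy study", {
  x <- toy_crt()
  # equal cluster weights: (0.2*4 + 0.75)/5
  expect_equal(mean(x$clusters$Yc), 0.31, tolerance = 1e-12)
  # equal participant weights
  expect_equal(pooled_individual_mean(x, 1), 0.748, tolerance = 1e-3)
  # geometric mean of the cluster-level outcomes
  expect_equal(exp(mean(log(x$clusters$Yc))), 0.26, tolerance = 5e-3)
})

test_that("aggregate_outcome is the weighted event sum", {
  expect_equal(aggregate_outcome(c(1, 0, 1)), 2 / 3)
  expect_equal(aggregate_outcome(rep(0, 7), runif(7)), 0)
  expect_equal(aggregate_outcome(c(1, 1, 0), c(0.5, 0.25, 0.25)), 0.75)
  expect_error(aggregate_outcome(c(1, 0), c(0.5, NA)), "individual")
  expect_error(aggregate_outcome(c(1, 0, 1), c(0.5, 0.5)), "one weight per")
})

test_that("analysis-weighted cluster means reproduce pooled individual means", {
  for (seed in 1:5) {
    d <- random_crt(J = 10, seed = seed)
    w <- analysis_weights(d, "individual")
    cl <- d$clusters
    for (a in 0:1) {
      expect_equal(
        sum(w * cl$Yc * (cl$A == a)) / sum(w * (cl$A == a)),
        pooled_individual_mean(d, a), tolerance = 1e-12)
    }
    expect_equal(sum(w), d$J)                      # normalization
    expect_equal(analysis_weights(d, "cluster"), rep(1, d$J))
  }
})

test_that("equal cluster sizes collapse the two target levels", {
  d <- random_crt(J = 8, equal_n = 15, seed = 3)
  expect_equal(analysis_weights(d, "individual"), rep(1, 8))
  u_c <- unadjusted_contrast(d, estimand_spec("cluster"))
  u_i <- unadjusted_contrast(d, estimand_spec("individual"))
  expect_equal(u_c$estimate, u_i$estimate, tolerance = 1e-13)
  # and the pooled mean equals the unweighted mean of cluster means
  expect_equal(mean(d$clusters$Yc[d$clusters$A == 1]),
               pooled_individual_mean(d, 1), tolerance = 1e-13)
})

test_that("validate_crt reports every violation and throws none", {
  expect_identical(validate_crt(random_crt(J = 20, seed = 9)), character(0))

  one_arm <- random_crt(J = 6, seed = 2)
  one_arm$clusters$A <- 1
  one_arm$individuals$A <- 1
  expect_match(validate_crt(one_arm), "all clusters in arm 1", all = FALSE)

  cont <- random_crt(J = 6, seed = 2)
  cont$individuals$Y[3] <- 0.5
  expect_match(validate_crt(cont), "non-binary outcome", all = FALSE)

  bad_pair <- random_crt(J = 6, seed = 2, paired = TRUE)
  bad_pair$clusters$pair_id[1] <- "p99"
  expect_match(validate_crt(bad_pair), "exactly 2", all = FALSE)

  mismatch <- random_crt(J = 6, seed = 2)
  mismatch$clusters$N[2] <- mismatch$clusters$N[2] + 1
  expect_match(validate_crt(mismatch), "size mismatch", all = FALSE)
})

test_that("cluster-only data support the cluster-level workflow", {
  d <- random_crt(J = 10, seed = 11)
  dc <- crt_data_clusters(d$clusters)
  expect_true(dc$cluster_only)
  expect_equal(pooled_individual_mean(dc, 1), pooled_individual_mean(d, 1))
  u1 <- unadjusted_contrast(dc, estimand_spec("individual"))
  u2 <- unadjusted_contrast(d, estimand_spec("individual"))
  expect_equal(u1$estimate, u2$estimate, tolerance = 1e-13)
  expect_error(hierarchical_tmle(dc, estimand_spec()), "individual-level")
  expect_error(care(dc), "individual-level")
  bad <- d$clusters; bad$Yc[1] <- 1.2
  expect_error(crt_data_clusters(bad), "0, 1")
})
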