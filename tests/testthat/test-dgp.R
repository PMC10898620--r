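test_that("simulated trials have the configured pair-matched structure", {
  d <- simulate_crt(dgp_config("sim1", J = 20, seed = 4))
  cl <- d$clusters
  expect_equal(d$J, 20)
  expect_equal(sum(cl$A == 1), 10)
  expect_true(all(cl$N >= 30))
  expect_length(unique(cl$pair_id), 10)
  expect_identical(validate_crt(d), character(0))
  # deterministic given the seed
  d2 <- simulate_crt(dgp_config("sim1", J = 20, seed = 4))
  expect_identical(d$individuals, d2$individuals)
  d3 <- simulate_crt(dgp_config("sim1", J = 20, seed = 5))
  expect_false(identical(d$clusters$Yc, d3$clusters$Yc))
  expect_error(dgp_config("sim1", J = 19), "even")

  s2 <- simulate_crt(dgp_config("sim2", J = 20, seed = 4))
  expect_identical(validate_crt(s2), character(0))
  expect_equal(sum(s2$clusters$A), 10)
})

test_that("the covariate hierarchy has the stated marginal moments", {
  # W1 ~ Norm(2*UE1, 0.35) with UE1 ~ Unif(-0.2, 1.5): E[W1] = 1.3
  d <- simulate_crt(dgp_config("sim1", J = 300, seed = 21))
  expect_equal(mean(tapply(d$individuals$W1, d$individuals$cluster_id, mean)),
               1.3, tolerance = 0.06)
  # cluster sizes truncated below at 30, centred near 150
  expect_gt(min(d$clusters$N), 29)
  expect_equal(mean(d$clusters$N), 155, tolerance = 10)
})

test_that("pair matching attains the minimum-cost perfect pairing", {
  # unique optimum by inspection
  p <- pair_match(c(0, 0.1, 5, 5.2))
  expect_equal(p[1], p[2])
  expect_equal(p[3], p[4])
  expect_true(p[1] != p[3])
  expect_error(pair_match(1:5), "odd")

  pair_cost <- function(values, pairs) {
    sum(vapply(unique(pairs), function(k) {
      abs(diff(values[pairs == k]))
    }, 0))
  }
  # exhaustive enumeration of perfect pairings as the oracle
  all_pairings <- function(idx) {
    if (!length(idx)) return(list(integer(0)))
    out <- list()
    for (m in idx[-1]) {
      rest <- setdiff(idx[-1], m)
      for (sub in all_pairings(rest)) {
        out[[length(out) + 1]] <- c(idx[1], m, sub)
      }
    }
    out
  }
  set.seed(8)
  for (J in c(4, 6, 8)) {
    v <- rnorm(J)
    best <- min(vapply(all_pairings(seq_len(J)), function(perm) {
      pairs <- integer(J)
      pairs[perm] <- rep(seq_len(J / 2), each = 2)
      pair_cost(v, pairs)
    }, 0))
    expect_equal(pair_cost(v, pair_match(v)), best, tolerance = 1e-12)
  }
  # on sorted input the optimum is adjacent pairing
  v <- sort(rnorm(20))
  expect_equal(pair_cost(v, pair_match(v)),
               sum(v[seq(2, 20, 2)] - v[seq(1, 19, 2)]), tolerance = 1e-12)
})

test_that("null-effect counterfactuals are coupled so true ratios are exactly 1", {
  for (study in c("sim1", "sim2")) {
    tr <- compute_truth(dgp_config(study, null_effect = TRUE, seed = 31,
                                   population_size = 200))
    expect_identical(tr$cluster_ratio, 1)
    expect_identical(tr$individual_ratio, 1)
    expect_identical(tr$geometric_ratio, 1)
  }
})

test_that("outcome risk declines with cluster size in the informative-size study", {
  d <- simulate_crt(dgp_config("sim2", J = 1000, seed = 17))
  cl <- d$clusters
  for (a in 0:1) {
    expect_lt(stats::cor(cl$N[cl$A == a], cl$Yc[cl$A == a],
                         method = "spearman"), -0.3)
  }
})

test_that("truth values are stable across seeds at the default population sizes", {
  t_a <- compute_truth(dgp_config("sim2", seed = 61, population_size = 1000))
  t_b <- compute_truth(dgp_config("sim2", seed = 62, population_size = 1000))
  expect_equal(t_a$cluster_ratio, t_b$cluster_ratio, tolerance = 0.03)
  expect_equal(t_a$individual_ratio, t_b$individual_ratio, tolerance = 0.03)
})
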