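test_that("unadjusted contrast of equal arm means is null on both scales", {
  d <- crt_from_means(means1 = c(0.2, 0.4), means0 = c(0.3, 0.3))
  r <- unadjusted_contrast(d, estimand_spec("cluster", "ratio"))
  expect_equal(r$estimate, 1, tolerance = 1e-12)
  dd <- unadjusted_contrast(d, estimand_spec("cluster", "difference"))
  expect_equal(dd$estimate, 0, tolerance = 1e-12)
})

test_that("unadjusted contrast equals the empty-adjustment TMLE", {
  for (seed in 1:10) {
    d <- random_crt(J = 10, seed = 100 + seed)
    for (lvl in c("cluster", "individual")) {
      es <- estimand_spec(lvl)
      expect_equal(unadjusted_contrast(d, es)$estimate,
                   cluster_tmle(d, es)$estimate, tolerance = 1e-10)
    }
  }
})

test_that("geometric-mean t-test targets the ratio of geometric means", {
  # control arm: the toy clusters (geometric mean 0.26)
  toy <- toy_crt(arm = 0L)$individuals[c("cluster_id", "A", "Y")]
  trt <- data.frame(cluster_id = rep(c("x1", "x2"), each = 10),
                    A = 1L, Y = rep(c(1L, 0L), c(4, 6)))
  d <- crt_data(rbind(toy, trt))
  g <- geometric_ttest(d)
  expect_equal(g$psi0, 0.26, tolerance = 5e-3)
  expect_equal(g$estimate, g$psi1 / g$psi0, tolerance = 1e-12)
  # arithmetic mean dominates the geometric mean in each arm (AM-GM)
  u <- unadjusted_contrast(d, estimand_spec("cluster"))
  expect_gte(u$psi1, g$psi1)
  expect_gte(u$psi0, g$psi0)
})

test_that("geometric-mean t-test flags degenerate and undefined inputs", {
  d <- crt_from_means(means1 = c(0.3, 0.3), means0 = c(0.3, 0.3))
  expect_warning(g <- geometric_ttest(d), "degenerate")
  expect_equal(g$estimate, 1)
  expect_true(is.nan(g$p_value))

  dz <- crt_from_means(means1 = c(0, 0.4), means0 = c(0.3, 0.2))
  expect_error(geometric_ttest(dz), "m01")  # names the zero cluster
})

test_that("CARE with an intercept-only regression uses the pooled rate", {
  d <- random_crt(J = 10, seed = 33)
  fit <- care(d)
  p_bar <- mean(d$individuals$Y)
  expect_equal(unname(fit$expected), d$clusters$N * p_bar, tolerance = 1e-8)
  expect_equal(unname(fit$residuals),
               (d$clusters$Yc) / p_bar, tolerance = 1e-8)
})

test_that("CARE is exactly null for mirrored arms", {
  base <- random_crt(J = 6, seed = 44)$individuals
  mirror <- base
  mirror$cluster_id <- paste0(mirror$cluster_id, "m")
  mirror$A <- 1L - base$A
  d <- crt_data(rbind(base, mirror))
  fit <- care(d, c("W1", "E1"))
  expect_equal(fit$estimate, 1, tolerance = 1e-10)
})

test_that("CARE rejects the arm in the adjustment set and zero-event clusters", {
  d <- random_crt(J = 8, seed = 13)
  expect_error(care(d, c("A", "W1")), "exclude")
  dz <- d
  dz$individuals$Y[dz$individuals$cluster_id == "c01"] <- 0L
  dz <- crt_data(dz$individuals)
  expect_error(care(dz), "c01")
})
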