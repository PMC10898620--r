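# Fixtures are built in code. random_crt() is deliberately independent of
# the package's simulation module: a plain hierarchical Bernoulli draw used
# to exercise estimator identities on arbitrary data.

random_crt <- function(J = 12, n_range = c(8, 25), seed = 1,
                       equal_n = NULL, paired = FALSE,
                       lp_fun = function(A, W1, W2, E1) {
                         -0.4 - 0.3 * A + 0.5 * W1 + 0.2 * E1
                       }) {
  set.seed(seed)
  n <- if (is.null(equal_n)) {
    sample(seq(n_range[1], n_range[2]), J, replace = TRUE)
  } else rep(equal_n, J)
  if (paired) {
    pair <- rep(seq_len(J / 2), each = 2)
    A <- as.vector(vapply(seq_len(J / 2), function(k) sample(c(1L, 0L)),
                          integer(2)))
  } else {
    pair <- rep(NA_character_, J)
    A <- sample(rep(c(1L, 0L), J / 2))
  }
  rows <- lapply(seq_len(J), function(j) {
    E1 <- rnorm(1)
    uw <- rnorm(1, 0, 0.6)
    W1 <- rnorm(n[j], uw, 0.8)
    W2 <- rnorm(n[j], 0, 1)
    Y <- as.integer(runif(n[j]) < plogis(lp_fun(A[j], W1, W2, E1)))
    data.frame(cluster_id = sprintf("c%02d", j),
               pair_id = if (paired) sprintf("p%02d", pair[j]) else NA,
               A = A[j], Y = Y, W1 = W1, W2 = W2, E1 = E1)
  })
  crt_data(do.call(rbind, rows))
}

# The five-cluster toy study: sizes 10, 10, 10, 10, 10000 with event counts
# 2, 2, 2, 2, 7500, illustrating the divergence of cluster-level and
# individual-level summary measures.
toy_crt <- function(arm = 1L) {
  sizes <- c(10, 10, 10, 10, 10000)
  events <- c(2, 2, 2, 2, 7500)
  rows <- lapply(1:5, function(j) {
    data.frame(cluster_id = paste0("t", j), A = arm,
               Y = c(rep(1L, events[j]), rep(0L, sizes[j] - events[j])))
  })
  crt_data(do.call(rbind, rows))
}

# Tiny deterministic trial with prescribed cluster-level outcome means.
crt_from_means <- function(means1, means0, n = 10) {
  mk <- function(m, a, off) {
    lapply(seq_along(m), function(j) {
      ev <- round(m[j] * n)
      data.frame(cluster_id = sprintf("m%02d", off + j), A = a,
                 Y = c(rep(1L, ev), rep(0L, n - ev)))
    })
  }
  crt_data(do.call(rbind, c(mk(means1, 1L, 0), mk(means0, 0L, length(means1)))))
}
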