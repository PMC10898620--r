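# Data-generating processes for the two benchmark simulation studies.
#
# Both emulate a pair-matched CRT with J = 20 health facilities of widely
# varying size. Study 1 has strong cluster-level heterogeneity driven by a
# shared latent factor; study 2 makes the outcome risk depend on cluster
# size, with a size-by-treatment interaction ("informative cluster size"),
# so the cluster-level and individual-level effects diverge.
#
# Distribution notation: Norm(a, b) is mean a, SD b throughout.

#' Configuration of a simulation study data-generating process
#'
#' @param study `"sim1"` (latent cluster-level heterogeneity, mean cluster
#'   size 150) or `"sim2"` (informative cluster size, mean size 400).
#' @param J Number of clusters in a simulated trial (must be even;
#'   clusters are pair-matched before randomization).
#' @param null_effect If `TRUE`, outcomes are generated with every
#'   treatment term set to zero, so the true effect is exactly null.
#' @param seed Integer seed; a given seed reproduces a dataset exactly.
#' @param population_size Number of clusters used to compute the true
#'   (finite-population) effect values from counterfactual outcomes;
#'   defaults to 2500 for `sim1` and 1000 for `sim2`.
#' @return An object of class `dgp_config`.
#' @export
dgp_config <- function(study = c("sim1", "sim2"), J = 20,
                       null_effect = FALSE, seed = 1,
                       population_size = NULL) {
  study <- match.arg(study)
  if (J %% 2 != 0) stop("J must be even: clusters are randomized within pairs")
  if (is.null(population_size)) {
    population_size <- if (study == "sim1") 2500 else 1000
  }
  if (population_size < J) stop("population_size must be at least J")
  structure(list(study = study, J = as.integer(J),
                 null_effect = isTRUE(null_effect),
                 seed = as.integer(seed),
                 population_size = as.integer(population_size)),
            class = "dgp_config")
}

# One cluster's covariates and outcome-model linear predictor pieces.
# Returns counterfactual outcomes under both arms, coupled through shared
# uniform draws, so the null variant satisfies Y(1) = Y(0) exactly.
.sim_cluster <- function(study, null_effect) {
  if (study == "sim1") {
    E1 <- stats::rnorm(1, 2, 1); E2 <- stats::rnorm(1, 0, 1)
    N <- max(30L, as.integer(round(stats::rnorm(1, 150, 80))))
    UE1 <- stats::runif(1, -0.2, 1.5); UE2 <- stats::runif(1, -0.5, 0.5)
    W <- cbind(W1 = stats::rnorm(N, 2 * UE1, 0.35),
               W2 = stats::rnorm(N, 4 * UE1, 0.9),
               W3 = stats::rnorm(N, UE2, 0.5),
               W4 = stats::rnorm(N, UE2, 0.5))
    base <- -0.75 + 0.8 * W[, "W1"] + 0.4 * W[, "W2"] - 0.3 * E1
    trt <- if (null_effect) 0 else -0.35 - 0.2 * W[, "W2"]
    E <- c(E1 = E1, E2 = E2)
  } else {
    E1 <- stats::rnorm(1, 0, 1); E2 <- stats::rnorm(1, 0, 1)
    N <- max(30L, as.integer(round(stats::rnorm(1, 400, 250))))
    UE1 <- stats::runif(1, -1, 1); UE2 <- stats::runif(1, -1, 1)
    UE3 <- stats::runif(1, -1, 1)
    W <- cbind(W1 = stats::rnorm(N, UE1, 0.5),
               W2 = stats::rnorm(N, UE2, 0.5),
               W3 = stats::rnorm(N, UE3, 0.5))
    Ntil <- N / 150
    base <- 0.5 + W[, "W1"] / 6 + W[, "W2"] / 2 + W[, "W3"] / 4 +
      E1 / 5 + E2 / 5 - Ntil / 8
    trt <- if (null_effect) 0 else -Ntil / 5
    E <- c(E1 = E1, E2 = E2)
  }
  U <- stats::runif(N)
  list(E = E, N = N, W = W,
       Y1 = as.integer(U < stats::plogis(base + trt)),
       Y0 = as.integer(U < stats::plogis(base)))
}

#' Optimal pairing of clusters on a scalar matching variable
#'
#' Returns the perfect pairing minimizing the total within-pair absolute
#' distance. For a scalar matching variable this optimum is attained by
#' pairing adjacent values after sorting, which is what nonbipartite
#' (minimum-weight perfect) matching reduces to on the line.
#'
#' @param values Numeric vector (even length) of the matching variable,
#'   one value per cluster.
#' @return Integer vector of pair indices (1, ..., `length(values)/2`)
#'   aligned with `values`.
#' @export
pair_match <- function(values) {
  n <- length(values)
  if (n %% 2 != 0) stop("cannot pair an odd number of clusters")
  ord <- order(values)
  pairs <- integer(n)
  pairs[ord] <- rep(seq_len(n / 2), each = 2)
  pairs
}

#' Simulate a pair-matched CRT from a benchmark data-generating process
#'
#' Draws `J` clusters from the configured study, pair-matches them on the
#' cluster-level covariate `E2`, randomizes one cluster of each pair to the
#' intervention (independently across pairs), and returns the observed
#' data. All randomness flows from `config$seed`.
#'
#' @param config A [dgp_config()].
#' @return A [crt_data] object with covariates `W1..W4, E1, E2` (`sim1`) or
#'   `W1..W3, E1, E2` (`sim2`), pair ids `p1..p(J/2)`, and binary outcomes.
#' @export
simulate_crt <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  set.seed(config$seed)
  J <- config$J
  draws <- replicate(J, .sim_cluster(config$study, config$null_effect),
                     simplify = FALSE)
  E2 <- vapply(draws, function(d) d$E[["E2"]], 0)
  pairs <- pair_match(E2)
  A <- integer(J)
  for (k in seq_len(J / 2)) {
    members <- which(pairs == k)
    first_treated <- stats::runif(1) < 0.5
    A[members] <- if (first_treated) c(1L, 0L) else c(0L, 1L)
  }
  rows <- lapply(seq_len(J), function(j) {
    d <- draws[[j]]
    df <- data.frame(cluster_id = sprintf("c%02d", j),
                     pair_id = sprintf("p%02d", pairs[j]),
                     A = A[j],
                     Y = if (A[j] == 1) d$Y1 else d$Y0)
    for (w in colnames(d$W)) df[[w]] <- d$W[, w]
    df$E1 <- d$E[["E1"]]; df$E2 <- d$E[["E2"]]
    df
  })
  crt_data(do.call(rbind, rows))
}

#' True effect values of a data-generating process
#'
#' Simulates a large population of clusters with both counterfactual
#' outcome vectors (the same uniform draws are used under both arms, so
#' under the null variant the counterfactuals coincide exactly) and
#' computes the finite-population values of the three target effects:
#' the cluster-level incidence ratio (equal cluster weights), the
#' individual-level risk ratio (equal participant weights), and the ratio
#' of geometric means of the cluster-level outcomes.
#'
#' @param config A [dgp_config()]; `population_size` clusters are drawn
#'   using `config$seed`.
#' @return An object of class `crt_truth`: a list with `cluster_ratio`,
#'   `individual_ratio`, `geometric_ratio`, the arm-specific means behind
#'   each, and the configuration. Clusters with a zero counterfactual mean
#'   in either arm are excluded from the geometric ratio (their log is
#'   undefined), with a warning.
#' @export
compute_truth <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  set.seed(config$seed)
  M <- config$population_size
  Yc1 <- Yc0 <- numeric(M)
  N <- integer(M)
  ev1 <- ev0 <- 0
  for (j in seq_len(M)) {
    d <- .sim_cluster(config$study, config$null_effect)
    Yc1[j] <- mean(d$Y1); Yc0[j] <- mean(d$Y0)
    ev1 <- ev1 + sum(d$Y1); ev0 <- ev0 + sum(d$Y0)
    N[j] <- d$N
  }
  ok <- Yc1 > 0 & Yc0 > 0
  if (!all(ok)) {
    warning(sum(!ok), " cluster(s) with a zero counterfactual mean ",
            "excluded from the geometric ratio")
  }
  structure(list(
    cluster_ratio = mean(Yc1) / mean(Yc0),
    individual_ratio = ev1 / ev0,
    geometric_ratio = exp(mean(log(Yc1[ok])) - mean(log(Yc0[ok]))),
    psi1_cluster = mean(Yc1), psi0_cluster = mean(Yc0),
    psi1_individual = ev1 / sum(N), psi0_individual = ev0 / sum(N),
    population_size = M, study = config$study,
    null_effect = config$null_effect, seed = config$seed
  ), class = "crt_truth")
}

#' @export
print.crt_truth <- function(x, digits = 4, ...) {
  cat(sprintf("True effects of %s%s (population of %d clusters):\n",
              x$study, if (x$null_effect) " under the null" else "",
              x$population_size))
  cat(sprintf("  cluster-level incidence ratio: %.*g\n",
              digits, x$cluster_ratio))
  cat(sprintf("  individual-level risk ratio:   %.*g\n",
              digits, x$individual_ratio))
  cat(sprintf("  geometric-mean ratio:          %.*g\n",
              digits, x$geometric_ratio))
  invisible(x)
}
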