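# Targeted maximum likelihood estimators for two-arm CRTs.
#
# Three implementations share one fluctuation logic:
#  * cluster-level TMLE: everything at the cluster level (aggregated data);
#  * hierarchical TMLE: outcome regression, propensity and fluctuation on
#    pooled individual rows, influence function aggregated to clusters;
#  * hybrid TMLE: individual-level outcome regression aggregated to an
#    initial cluster-level estimator, then the cluster-level steps.
#
# All fitting routines accept a `train` set of clusters so that Adaptive
# Prespecification can reuse them for leave-one-cluster/pair-out
# cross-validation: coefficients come from the training clusters, and
# predictions / influence-function contributions are produced for every
# cluster.

.bound <- function(p, lo = 1e-6) pmin(pmax(p, lo), 1 - lo)

# lean logistic helpers for the cross-validation hot path
.expit <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

.trunc_ps <- function(p, quiet = FALSE) {
  out <- pmin(pmax(p, 0.05), 0.95)
  if (!quiet && any(out != p)) {
    warning("propensity estimates truncated to [0.05, 0.95]")
  }
  out
}

# Weighted logistic maximum likelihood on a prebuilt design matrix, by
# Newton-Raphson. Accepts fractional responses in [0, 1] (cluster-level
# outcomes) and an offset (the TMLE fluctuation). Returns the coefficient
# vector, or NULL on failure (singularity, separation, non-convergence) so
# callers can fall back to the unadjusted candidate. Much leaner than
# glm.fit, which matters inside leave-one-cluster-out cross-validation.
.logit_irls <- function(X, y, weights = NULL, offset = NULL,
                        maxit = 60, tol = 1e-10) {
  if (is.null(weights)) weights <- rep(1, length(y))
  if (is.null(offset)) offset <- 0
  b <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- offset + drop(X %*% b)
    mu <- .expit(eta)
    v <- weights * mu * (1 - mu)
    if (!all(is.finite(v)) || max(v) < 1e-12) return(NULL)  # separation
    info <- crossprod(X, X * v)
    score <- crossprod(X, weights * (y - mu))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    # dampen huge jumps (quasi-separated fits) instead of diverging
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    b <- b + drop(step)
    if (max(abs(step)) < tol) return(stats::setNames(b, colnames(X)))
  }
  NULL
}

.glm_try <- function(X, y, weights = NULL, offset = NULL) {
  .logit_irls(X, y, weights = weights, offset = offset)
}

.design <- function(df, adj, arm = TRUE) {
  stopifnot(all(adj %in% names(df)))
  base <- if (arm) cbind(`(Intercept)` = rep(1, nrow(df)), A = df$A) else
    cbind(`(Intercept)` = rep(1, nrow(df)))
  if (length(adj)) cbind(base, as.matrix(df[adj])) else base
}

# Cluster-level TMLE engine. `cl` is the clusters data.frame, `w` the
# analysis weights (sum J). `init`, when given, supplies the initial
# outcome-regression predictions (hybrid TMLE); otherwise a weighted
# logistic regression of Yc on A and `outcome_adj` is fitted on `train`.
.ctmle_fit <- function(cl, w, outcome_adj, ps_adj, train = NULL,
                       init = NULL, quiet = FALSE) {
  J <- nrow(cl)
  if (is.null(train)) train <- seq_len(J)
  Yc <- cl$Yc
  A <- cl$A

  if (is.null(init)) {
    Xo <- .design(cl, outcome_adj)
    b <- .glm_try(Xo[train, , drop = FALSE], Yc[train], weights = w[train])
    if (is.null(b) && length(outcome_adj)) {
      if (!quiet) {
        warning("cluster-level outcome regression failed for {",
                paste(outcome_adj, collapse = ", "),
                "}; falling back to the unadjusted candidate")
      }
      Xo <- .design(cl, character())
      b <- .glm_try(Xo[train, , drop = FALSE], Yc[train], weights = w[train])
    }
    if (is.null(b)) stop("cluster-level outcome regression failed")
    X1 <- Xo; X1[, "A"] <- 1
    X0 <- Xo; X0[, "A"] <- 0
    mu_obs <- .expit(drop(Xo %*% b))
    mu1 <- .expit(drop(X1 %*% b))
    mu0 <- .expit(drop(X0 %*% b))
  } else {
    mu_obs <- init$mu_obs; mu1 <- init$mu1; mu0 <- init$mu0
  }

  if (length(ps_adj)) {
    Xp <- .design(cl, ps_adj, arm = FALSE)
    bp <- .glm_try(Xp[train, , drop = FALSE], A[train])
    if (is.null(bp)) {
      if (!quiet) warning("propensity regression failed; using known 0.5")
      pi1 <- rep(0.5, J)
    } else {
      pi1 <- .trunc_ps(.expit(drop(Xp %*% bp)), quiet = quiet)
    }
  } else {
    pi1 <- rep(0.5, J)  # known by design in a balanced CRT
  }
  H1 <- (A == 1) / pi1
  H0 <- (A == 0) / (1 - pi1)

  off <- .logit(.bound(mu_obs))
  eps <- .glm_try(cbind(H1 = H1, H0 = H0)[train, , drop = FALSE], Yc[train],
                  weights = w[train], offset = off[train])
  if (is.null(eps)) eps <- c(H1 = 0, H0 = 0)
  mu1s <- .expit(.logit(.bound(mu1)) + eps[1] / pi1)
  mu0s <- .expit(.logit(.bound(mu0)) + eps[2] / (1 - pi1))
  mu_obs_s <- mu0s; mu_obs_s[A == 1] <- mu1s[A == 1]

  psi1 <- stats::weighted.mean(mu1s[train], w[train])
  psi0 <- stats::weighted.mean(mu0s[train], w[train])
  # ratio-form influence function: the analysis weight multiplies the whole
  # centered contribution, so the covariance between cluster size and
  # outcome (informative cluster size) enters the variance
  D1 <- w * (H1 * (Yc - mu_obs_s) + mu1s - psi1)
  D0 <- w * (H0 * (Yc - mu_obs_s) + mu0s - psi0)

  list(psi1 = psi1, psi0 = psi0, D1 = D1, D0 = D0,
       mu1s = mu1s, mu0s = mu0s, mu_obs_s = mu_obs_s,
       H1 = H1, H0 = H0, pi1 = pi1, eps = eps)
}

# Individual-level (pooled) outcome regression with optional restriction to
# training clusters; returns predictions for every individual.
.ind_outcome_fit <- function(ind, outcome_adj, rows, weights = NULL,
                             quiet = FALSE) {
  Xo <- .design(ind, outcome_adj)
  b <- .glm_try(Xo[rows, , drop = FALSE], ind$Y[rows],
                weights = weights[rows])
  if (is.null(b) && length(outcome_adj)) {
    if (!quiet) {
      warning("individual-level outcome regression failed for {",
              paste(outcome_adj, collapse = ", "),
              "}; falling back to the unadjusted candidate")
    }
    Xo <- .design(ind, character())
    b <- .glm_try(Xo[rows, , drop = FALSE], ind$Y[rows],
                  weights = weights[rows])
  }
  if (is.null(b)) stop("individual-level outcome regression failed")
  X1 <- Xo; X1[, "A"] <- 1
  X0 <- Xo; X0[, "A"] <- 0
  list(mu_obs = .expit(drop(Xo %*% b)),
       mu1 = .expit(drop(X1 %*% b)),
       mu0 = .expit(drop(X0 %*% b)))
}

# Hierarchical TMLE engine. Fits everything on pooled individual rows of the
# training clusters; aggregates the influence function to clusters.
.htmle_fit <- function(data, target, outcome_adj, ps_adj, train = NULL,
                       quiet = FALSE) {
  cl <- data$clusters
  ind <- data$individuals
  J <- data$J
  if (is.null(train)) train <- seq_len(J)
  cid <- match(ind$cluster_id, cl$cluster_id)
  rows <- cid %in% train

  # Individual-level analysis weights J/NT x 1/alpha_ij x alpha_ij: constant
  # for the individual-level target, proportional to alpha_ij (1/N_j by
  # default) for the cluster-level target so that every cluster contributes
  # equally to each step -- initial fit, fluctuation, and aggregation.
  u <- if (target == "cluster") data$alpha * data$NT / J else
    rep(1, nrow(ind))

  f <- .ind_outcome_fit(ind, outcome_adj, rows, weights = u, quiet = quiet)

  if (length(ps_adj)) {
    Xp <- .design(ind, ps_adj, arm = FALSE)
    bp <- .glm_try(Xp[rows, , drop = FALSE], ind$A[rows], weights = u[rows])
    if (is.null(bp)) {
      if (!quiet) warning("propensity regression failed; using known 0.5")
      pi1 <- rep(0.5, nrow(ind))
    } else {
      pi1 <- .trunc_ps(.expit(drop(Xp %*% bp)), quiet = quiet)
    }
  } else {
    pi1 <- rep(0.5, nrow(ind))
  }
  H1 <- (ind$A == 1) / pi1
  H0 <- (ind$A == 0) / (1 - pi1)

  off <- .logit(.bound(f$mu_obs))
  eps <- .glm_try(cbind(H1 = H1, H0 = H0)[rows, , drop = FALSE],
                  ind$Y[rows], weights = u[rows], offset = off[rows])
  if (is.null(eps)) eps <- c(H1 = 0, H0 = 0)
  mu1s <- .expit(.logit(.bound(f$mu1)) + eps[1] / pi1)
  mu0s <- .expit(.logit(.bound(f$mu0)) + eps[2] / (1 - pi1))
  mu_obs_s <- mu0s; mu_obs_s[ind$A == 1] <- mu1s[ind$A == 1]

  fcid <- factor(cid, levels = seq_len(J))
  if (target == "individual") {
    psi1 <- mean(mu1s[rows]); psi0 <- mean(mu0s[rows])
    scale_j <- J / data$NT          # per-individual weight in the cluster IF
    Dij1 <- H1 * (ind$Y - mu_obs_s) + mu1s - psi1
    Dij0 <- H0 * (ind$Y - mu_obs_s) + mu0s - psi0
    D1 <- scale_j * as.numeric(rowsum(Dij1, fcid))
    D0 <- scale_j * as.numeric(rowsum(Dij0, fcid))
  } else {
    agg1 <- as.numeric(rowsum(data$alpha * mu1s, fcid))
    agg0 <- as.numeric(rowsum(data$alpha * mu0s, fcid))
    psi1 <- mean(agg1[train]); psi0 <- mean(agg0[train])
    Dij1 <- H1 * (ind$Y - mu_obs_s) + mu1s - psi1
    Dij0 <- H0 * (ind$Y - mu_obs_s) + mu0s - psi0
    D1 <- as.numeric(rowsum(data$alpha * Dij1, fcid))
    D0 <- as.numeric(rowsum(data$alpha * Dij0, fcid))
  }

  list(psi1 = psi1, psi0 = psi0, D1 = D1, D0 = D0,
       mu1s = mu1s, mu0s = mu0s, mu_obs_s = mu_obs_s,
       H1 = H1, H0 = H0, pi1 = pi1, eps = eps)
}

# Aggregate individual-level outcome-regression predictions to the
# cluster level (initial estimator of the hybrid TMLE).
.aggregate_init <- function(data, outcome_adj, train = NULL, quiet = FALSE) {
  cl <- data$clusters
  ind <- data$individuals
  if (is.null(train)) train <- seq_len(data$J)
  cid <- match(ind$cluster_id, cl$cluster_id)
  rows <- cid %in% train
  f <- .ind_outcome_fit(ind, outcome_adj, rows, quiet = quiet)
  fcid <- factor(cid, levels = seq_len(data$J))
  list(mu_obs = as.numeric(rowsum(data$alpha * f$mu_obs, fcid)),
       mu1 = as.numeric(rowsum(data$alpha * f$mu1, fcid)),
       mu0 = as.numeric(rowsum(data$alpha * f$mu0, fcid)))
}

.check_binary_outcome <- function(data) {
  if (data$cluster_only) {
    if (any(data$clusters$Yc < 0 | data$clusters$Yc > 1)) {
      stop("cluster-level outcomes must lie in [0, 1]; the logistic ",
           "fluctuation is defined for bounded outcomes only")
    }
  } else if (!all(data$individuals$Y %in% c(0, 1))) {
    stop("TMLE fluctuation requires a binary individual-level outcome; ",
         "continuous outcomes are out of scope")
  }
  invisible(TRUE)
}

#' Cluster-level TMLE for a CRT effect
#'
#' Targeted maximum likelihood estimation on data aggregated to the cluster
#' level. An initial weighted logistic regression of the cluster-level
#' outcome \eqn{Y^c} on the arm and `outcome_adj` is updated ("fluctuated")
#' on the logit scale using the clever covariates
#' \eqn{H(a) = 1(A=a)/\hat\pi(a|\cdot)}, solving the efficient score
#' equation. The propensity is the known design value 0.5 when `ps_adj` is
#' empty and is estimated (then truncated to \[0.05, 0.95\]) otherwise.
#' Targeting the individual-level effect applies analysis weights
#' \eqn{J N_j / N_T} in every step (initial fit, fluctuation, averaging);
#' with the cluster-level target all weights are 1. Inference is by the
#' influence function with a t reference distribution on `J - 2` degrees of
#' freedom (or `J/2 - 1` when matched pairs are kept).
#'
#' With empty adjustment sets the estimator reduces exactly to the
#' unadjusted contrast of (weighted) arm-specific means.
#'
#' @param data A [crt_data] object.
#' @param estimand An [estimand_spec()].
#' @param outcome_adj Character vector of cluster-level adjustment
#'   covariates for the outcome regression (columns of `data$clusters`:
#'   `E*` covariates, `W*c` means, or `N`); empty for no adjustment.
#' @param ps_adj Character vector of cluster-level covariates for the
#'   propensity score; empty uses the known value 0.5.
#' @param conf_level Confidence level for the interval.
#' @return A `crt_effect` object.
#' @references The estimator follows the standard TMLE template for
#'   randomized trials with the cluster as the unit of analysis.
#' @export
cluster_tmle <- function(data, estimand = estimand_spec(),
                         outcome_adj = character(), ps_adj = character(),
                         conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"), inherits(estimand, "estimand_spec"))
  .check_binary_outcome(data)
  w <- analysis_weights(data, estimand$level)
  f <- .ctmle_fit(data$clusters, w, outcome_adj, ps_adj)
  contrast <- .if_contrast(f$psi1, f$psi0, f$D1, f$D0, estimand,
                           data$clusters, conf_level)
  .effect_estimate("Cluster-level TMLE", estimand, f$psi1, f$psi0, contrast,
                   extra = list(outcome_adj = outcome_adj, ps_adj = ps_adj,
                                eps = f$eps))
}

#' Hierarchical TMLE for a CRT effect
#'
#' Pools participant-level rows across clusters to fit the individual-level
#' outcome regression and (optionally) propensity score, fluctuates at the
#' individual level, then aggregates: for the individual-level target,
#' \eqn{\hat\psi(a)} is the mean targeted prediction over all participants
#' and the cluster influence function is
#' \eqn{D_j = \sum_i (J/N_T) D_{ij}}; for the cluster-level target the
#' targeted predictions are aggregated within clusters with the
#' \eqn{\alpha_{ij}} weights before averaging across clusters, and
#' \eqn{D_j = \sum_i \alpha_{ij} D_{ij}}. The variance is the sample
#' variance of the cluster-level influence function over the `J` independent
#' units.
#'
#' @inheritParams cluster_tmle
#' @param outcome_adj Character vector of individual-level adjustment
#'   covariates (`W*` columns; cluster-level `E*` columns may be included).
#' @param ps_adj Covariates for the individual-level propensity score; empty
#'   uses the known 0.5.
#' @return A `crt_effect` object.
#' @export
hierarchical_tmle <- function(data, estimand = estimand_spec(),
                              outcome_adj = character(),
                              ps_adj = character(), conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"), inherits(estimand, "estimand_spec"))
  if (data$cluster_only) {
    stop("hierarchical TMLE requires individual-level records")
  }
  .check_binary_outcome(data)
  f <- .htmle_fit(data, estimand$level, outcome_adj, ps_adj)
  contrast <- .if_contrast(f$psi1, f$psi0, f$D1, f$D0, estimand,
                           data$clusters, conf_level)
  .effect_estimate("Hierarchical TMLE", estimand, f$psi1, f$psi0, contrast,
                   extra = list(outcome_adj = outcome_adj, ps_adj = ps_adj,
                                eps = f$eps))
}

#' Hybrid TMLE for a CRT effect
#'
#' Fits the individual-level outcome regression on pooled rows, aggregates
#' its predictions within clusters
#' (\eqn{\hat\mu^c_j = \sum_i \alpha_{ij} \hat\mu(A_j, E_j, W_{ij})}) to
#' form the initial cluster-level estimator, and then proceeds exactly as
#' the cluster-level TMLE: cluster-level propensity, cluster-level
#' fluctuation with analysis weights, cluster-level influence function.
#'
#' @inheritParams cluster_tmle
#' @param outcome_adj Individual-level adjustment covariates for the pooled
#'   outcome regression.
#' @param ps_adj Cluster-level covariates for the propensity score; empty
#'   uses the known 0.5.
#' @return A `crt_effect` object.
#' @export
hybrid_tmle <- function(data, estimand = estimand_spec(),
                        outcome_adj = character(), ps_adj = character(),
                        conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"), inherits(estimand, "estimand_spec"))
  if (data$cluster_only) stop("hybrid TMLE requires individual-level records")
  .check_binary_outcome(data)
  w <- analysis_weights(data, estimand$level)
  init <- .aggregate_init(data, outcome_adj)
  f <- .ctmle_fit(data$clusters, w, character(), ps_adj, init = init)
  contrast <- .if_contrast(f$psi1, f$psi0, f$D1, f$D0, estimand,
                           data$clusters, conf_level)
  .effect_estimate("Hybrid TMLE", estimand, f$psi1, f$psi0, contrast,
                   extra = list(outcome_adj = outcome_adj, ps_adj = ps_adj,
                                eps = f$eps))
}
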