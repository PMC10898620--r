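# Classic cluster-level comparators: unadjusted contrast of arm means,
# geometric-mean log-t-test, and the covariate-adjusted residuals estimator.

#' Unadjusted contrast of arm-specific cluster means
#'
#' Contrasts the (analysis-weighted) arm-specific means of the cluster-level
#' outcomes. With the cluster-level target every cluster counts equally;
#' with the individual-level target the weights \eqn{J N_j / N_T} make the
#' weighted cluster means reproduce the pooled participant-level means.
#' Ratio-scale inference is by the delta method on the log scale with the
#' influence function of the arm means; difference-scale inference uses the
#' same influence functions additively. This estimator is the special case
#' of the cluster-level TMLE with empty adjustment sets.
#'
#' @inheritParams cluster_tmle
#' @return A `crt_effect` object.
#' @export
unadjusted_contrast <- function(data, estimand = estimand_spec(),
                                conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"), inherits(estimand, "estimand_spec"))
  cl <- data$clusters
  w <- analysis_weights(data, estimand$level)
  A <- cl$A; Yc <- cl$Yc
  if (!any(A == 1) || !any(A == 0)) stop("both arms must be non-empty")
  psi1 <- sum(w * Yc * (A == 1)) / sum(w * (A == 1))
  psi0 <- sum(w * Yc * (A == 0)) / sum(w * (A == 0))
  if (estimand$scale == "ratio" && (psi1 <= 0 || psi0 <= 0)) {
    stop("zero arm mean; the ratio contrast is undefined")
  }
  pi1 <- mean(A == 1)   # empirical allocation: share of clusters in arm 1
  H1 <- (A == 1) / pi1
  H0 <- (A == 0) / (1 - pi1)
  mu_at_A <- ifelse(A == 1, psi1, psi0)
  D1 <- w * (H1 * (Yc - mu_at_A))   # centered: mu*(a) is the arm mean itself
  D0 <- w * (H0 * (Yc - mu_at_A))
  contrast <- .if_contrast(psi1, psi0, D1, D0, estimand, cl, conf_level)
  .effect_estimate("Unadjusted contrast", estimand, psi1, psi0, contrast)
}

#' Geometric-mean ratio via the log-transformed t-test
#'
#' Takes the log of each cluster-level outcome, averages within arm, and
#' applies Welch's two-sample t-test to the difference of arm means.
#' Exponentiating the estimate and interval targets the ratio of the
#' geometric means of the cluster-level outcomes -- a different estimand
#' from the ratio of arithmetic means, and typically further from 1.
#'
#' @param data A [crt_data] object. All cluster-level outcomes must be
#'   strictly positive (a cluster with no events has no log outcome; use
#'   the arithmetic-scale contrast instead).
#' @param conf_level Confidence level.
#' @return A `crt_effect` object (`psi1`, `psi0` are the arm-specific
#'   geometric means; `se` is on the log scale).
#' @export
geometric_ttest <- function(data, conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"))
  cl <- data$clusters
  if (any(cl$Yc <= 0)) {
    stop("geometric-mean ratio undefined: non-positive cluster outcomes in ",
         paste(cl$cluster_id[cl$Yc <= 0], collapse = ", "))
  }
  l1 <- log(cl$Yc[cl$A == 1]); l0 <- log(cl$Yc[cl$A == 0])
  est <- exp(mean(l1) - mean(l0))
  tt <- tryCatch(stats::t.test(l1, l0, conf.level = conf_level),
                 error = function(e) NULL)
  if (is.null(tt)) {
    warning("degenerate log outcomes (zero variance); p-value undefined")
    res <- list(estimate = est, se = 0, ci_lo = est, ci_hi = est,
                statistic = NaN, df = NA_real_, p_value = NaN,
                if_contrast = NULL, if1 = NULL, if0 = NULL,
                units = cl$cluster_id)
  } else {
    res <- list(estimate = est, se = unname(tt$stderr),
                ci_lo = exp(tt$conf.int[1]), ci_hi = exp(tt$conf.int[2]),
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, if_contrast = NULL,
                if1 = NULL, if0 = NULL, units = cl$cluster_id)
  }
  est_obj <- .effect_estimate(
    "Geometric-mean t-test",
    estimand_spec(level = "cluster", scale = "ratio"),
    exp(mean(l1)), exp(mean(l0)), res)
  est_obj
}

#' Covariate-adjusted residuals estimator (CARE)
#'
#' Fits a pooled individual-level logistic regression of the outcome on the
#' chosen baseline covariates -- never on the randomized arm -- and compares
#' each cluster's observed event count \eqn{d_j} with its model-expected
#' count \eqn{e_j} through the ratio residual \eqn{R_j = d_j/e_j}. A
#' two-sample t-test on the log residuals contrasts the arms; after
#' exponentiation this targets the ratio of geometric means of the
#' cluster-level outcomes.
#'
#' @param data A [crt_data] object with individual-level records.
#' @param adjustment Character vector of covariate names (individual-level
#'   `W*` and/or cluster-level `E*`); must not include the arm.
#' @param conf_level Confidence level.
#' @return A `crt_effect` object; `psi1`, `psi0` are the arm-specific
#'   geometric means of the ratio residuals.
#' @export
care <- function(data, adjustment = character(), conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"))
  if (data$cluster_only) stop("CARE requires individual-level records")
  if ("A" %in% adjustment) {
    stop("the outcome regression in CARE must exclude the randomized arm")
  }
  ind <- data$individuals
  cl <- data$clusters
  X <- .design(ind, adjustment, arm = FALSE)
  b <- .glm_try(X, ind$Y)
  if (is.null(b)) stop("CARE outcome regression failed")
  fitted <- stats::plogis(drop(X %*% b))
  fcid <- factor(ind$cluster_id, levels = cl$cluster_id)
  e_j <- as.numeric(rowsum(fitted, fcid))
  d_j <- as.numeric(rowsum(ind$Y, fcid))
  if (any(d_j == 0)) {
    stop("cluster(s) with no events (",
         paste(cl$cluster_id[d_j == 0], collapse = ", "),
         "): the log ratio residual is undefined; consider an ",
         "arithmetic-residual analysis")
  }
  lr <- log(d_j / e_j)
  l1 <- lr[cl$A == 1]; l0 <- lr[cl$A == 0]
  tt <- stats::t.test(l1, l0, var.equal = TRUE, conf.level = conf_level)
  res <- list(estimate = exp(mean(l1) - mean(l0)), se = unname(tt$stderr),
              ci_lo = exp(tt$conf.int[1]), ci_hi = exp(tt$conf.int[2]),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value, if_contrast = NULL,
              if1 = NULL, if0 = NULL, units = cl$cluster_id)
  out <- .effect_estimate(
    "Covariate-adjusted residuals estimator",
    estimand_spec(level = "cluster", scale = "ratio"),
    exp(mean(l1)), exp(mean(l0)), res,
    extra = list(adjustment = adjustment,
                 residuals = stats::setNames(d_j / e_j, cl$cluster_id),
                 expected = stats::setNames(e_j, cl$cluster_id),
                 observed = stats::setNames(d_j, cl$cluster_id)))
  out
}
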