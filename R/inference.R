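#' Influence-function inference for a ratio contrast (delta method)
#'
#' Given arm-specific estimates and their per-unit influence-function (IF)
#' contributions, forms the log-ratio IF
#' \eqn{D_{\log} = D(1)/\psi(1) - D(0)/\psi(0)}, estimates the log-scale
#' standard error as \eqn{\sqrt{\widehat{Var}(D_{\log})/n}} (sample variance
#' with \eqn{n-1} denominator over the \eqn{n} independent units), and tests
#' the null of no effect with a t reference distribution.
#'
#' @param psi1,psi0 Arm-specific point estimates (must be positive).
#' @param if1,if0 Numeric vectors of per-unit IF contributions for `psi1`
#'   and `psi0` (same length, one entry per independent unit).
#' @param df Degrees of freedom of the t reference distribution
#'   (conventionally `J - 2`, or `J/2 - 1` when matched pairs are kept).
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `estimate` (the ratio), `se` (log scale), `ci_lo`,
#'   `ci_hi`, `statistic`, `df`, `p_value`, and `if_contrast` (the per-unit
#'   log-ratio IF). The confidence interval is a symmetric t interval on the
#'   log scale, exponentiated.
#' @export
delta_ratio <- function(psi1, psi0, if1, if0, df, conf_level = 0.95) {
  if (psi1 <= 0 || psi0 <= 0) {
    stop("ratio contrast requires positive arm means; got psi1 = ", psi1,
         ", psi0 = ", psi0)
  }
  n <- length(if1)
  if (length(if0) != n) stop("if1 and if0 must have the same length")
  if (n < 3) stop("need at least 3 independent units for variance estimation")
  d_log <- if1 / psi1 - if0 / psi0
  se <- sqrt(stats::var(d_log) / n)
  est <- psi1 / psi0
  if (se <= .Machine$double.eps) {
    if (abs(log(est)) <= .Machine$double.eps^0.5) {
      tstat <- 0; p <- 1   # exactly null with no variability: no evidence
    } else {
      warning("zero influence-function variance; p-value undefined")
      tstat <- NaN; p <- NaN
    }
  } else {
    tstat <- log(est) / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  tc <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  list(estimate = est, se = se,
       ci_lo = exp(log(est) - tc * se), ci_hi = exp(log(est) + tc * se),
       statistic = tstat, df = df, p_value = p, if_contrast = d_log)
}

#' Influence-function inference for a difference contrast
#'
#' @inheritParams delta_ratio
#' @return A list with the same elements as [delta_ratio()] but on the
#'   additive scale (`se` is absolute; the CI is `estimate +/- t * se`).
#' @export
delta_difference <- function(psi1, psi0, if1, if0, df, conf_level = 0.95) {
  n <- length(if1)
  if (length(if0) != n) stop("if1 and if0 must have the same length")
  if (n < 3) stop("need at least 3 independent units for variance estimation")
  d <- if1 - if0
  se <- sqrt(stats::var(d) / n)
  est <- psi1 - psi0
  if (se <= .Machine$double.eps) {
    warning("zero influence-function variance; p-value undefined")
    tstat <- NaN; p <- NaN
  } else {
    tstat <- est / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
  }
  tc <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  list(estimate = est, se = se,
       ci_lo = est - tc * se, ci_hi = est + tc * se,
       statistic = tstat, df = df, p_value = p, if_contrast = d)
}

#' Pool cluster-level influence functions to matched pairs
#'
#' When the matched pairs used for randomization are preserved in the
#' analysis, the pair is the independent unit. Each pair's IF contribution
#' is the average of its two clusters' contributions, so that the grand mean
#' (the estimator's linear expansion) is unchanged and, for independent
#' pairs, the pair-level variance over `J/2` units reproduces the
#' cluster-level variance over `J` units.
#'
#' @param if_values Numeric vector of per-cluster IF contributions.
#' @param pair_id Pair identifier per cluster (no missing values; each id
#'   shared by exactly two clusters).
#' @return Numeric vector of per-pair IF contributions, named by pair id.
#' @export
pool_pairs <- function(if_values, pair_id) {
  if (anyNA(pair_id)) stop("every cluster must belong to a pair")
  sizes <- table(pair_id)
  if (any(sizes != 2)) {
    stop("pair ids must each cover exactly 2 clusters; offending: ",
         paste(names(sizes)[sizes != 2], collapse = ", "))
  }
  out <- tapply(if_values, pair_id, mean)
  stats::setNames(as.numeric(out), names(out))
}

# Shared finishing step for all IF-based estimators: collapse to pairs when
# matching is kept, pick the t df, and run the requested contrast.
.if_contrast <- function(psi1, psi0, if1, if0, estimand, clusters,
                         conf_level = 0.95) {
  if (estimand$matching == "keep") {
    pid <- clusters$pair_id
    if1 <- pool_pairs(if1, pid)
    if0 <- pool_pairs(if0, pid)
    units <- names(if1)
    df <- length(if1) - 1
  } else {
    units <- clusters$cluster_id
    df <- nrow(clusters) - 2
  }
  res <- if (estimand$scale == "ratio") {
    delta_ratio(psi1, psi0, if1, if0, df, conf_level)
  } else {
    delta_difference(psi1, psi0, if1, if0, df, conf_level)
  }
  res$if1 <- if1
  res$if0 <- if0
  res$units <- units
  res
}

# Assemble the common effect-estimate container.
.effect_estimate <- function(estimator, estimand, psi1, psi0, contrast,
                             selection = NULL, extra = NULL) {
  out <- c(list(estimator = estimator,
                level = estimand$level, scale = estimand$scale,
                matching = estimand$matching,
                psi1 = psi1, psi0 = psi0),
           contrast[c("estimate", "se", "ci_lo", "ci_hi", "statistic",
                      "df", "p_value", "if1", "if0", "if_contrast", "units")],
           list(selection = selection))
  if (!is.null(extra)) out <- c(out, extra)
  structure(out, class = "crt_effect")
}

#' @export
print.crt_effect <- function(x, digits = 4, ...) {
  cat(x$estimator, "for the", x$level, "level effect\n")
  cat(sprintf("  psi(1) = %.*g, psi(0) = %.*g\n",
              digits, x$psi1, digits, x$psi0))
  lab <- if (x$scale == "ratio") "ratio" else "difference"
  cat(sprintf("  %s = %.*g  (95%% CI %.*g to %.*g)\n", lab,
              digits, x$estimate, digits, x$ci_lo, digits, x$ci_hi))
  selab <- if (x$scale == "ratio") "SE (log scale)" else "SE"
  cat(sprintf("  %s = %.*g, t = %.*g on %g df, p = %.*g\n", selab,
              digits, x$se, digits, x$statistic, x$df, digits, x$p_value))
  if (!is.null(x$selection)) {
    cat("  adaptive prespecification: outcome = {",
        paste(x$selection$outcome, collapse = ", "), "}, propensity = {",
        paste(x$selection$propensity, collapse = ", "), "}\n")
  }
  invisible(x)
}
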