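# Replication harness: run a set of estimators over many simulated trials
# and summarize their operating characteristics (mean point estimate, bias,
# between-replicate SD and mean SE on the log scale, CI coverage, and the
# rejection rate, i.e. power under an effect or Type-I error under the
# null).

#' Declare an estimator for a simulation study
#'
#' @param name Label used in the summary table.
#' @param fn Function of one argument (a [crt_data] object) returning an
#'   estimate object with elements `estimate`, `ci_lo`, `ci_hi`, `p_value`,
#'   `se` (log scale for ratio estimators), and optionally `selection`
#'   (as produced by [adaptive_prespec()]).
#' @param truth Which true effect the estimator targets:
#'   `"cluster_ratio"`, `"individual_ratio"`, or `"geometric_ratio"`.
#' @return An object of class `estimator_spec`.
#' @export
estimator_spec <- function(name, fn,
                           truth = c("cluster_ratio", "individual_ratio",
                                     "geometric_ratio")) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn, truth = match.arg(truth)),
            class = "estimator_spec")
}

#' Run a simulation study
#'
#' Generates `R` replicate trials from the configured data-generating
#' process (replicate `r` uses seed `base_seed + r`), applies every
#' estimator to each, and aggregates operating characteristics against each
#' estimator's own target effect. Replicates where an estimator fails (e.g.
#' a cluster with no events for a log-scale estimator) are recorded and
#' excluded from that estimator's aggregates. The run is deterministic
#' given `base_seed`.
#'
#' @param config A [dgp_config()] describing the trial-generating process.
#' @param estimators List of [estimator_spec()] objects.
#' @param R Number of replicates (at least 2).
#' @param truth A `crt_truth` object from [compute_truth()], or `NULL`
#'   under the null (all true ratios are exactly 1).
#' @param base_seed Base seed; defaults to `config$seed`.
#' @param alpha_level Significance level for the rejection rate.
#' @return A data.frame of class `crt_sim_summary` with one row per
#'   estimator: `pt` (mean point estimate, ratio scale), `bias`
#'   (`pt - truth`), `sigma` (SD of log estimates), `sigma_hat` (mean
#'   log-scale SE), `coverage`, `reject`, `n_used`, `n_fail`. Adaptive
#'   selection labels per replicate are kept in `attr(, "selections")`.
#' @export
run_study <- function(config, estimators, R, truth = NULL,
                      base_seed = NULL, alpha_level = 0.05) {
  stopifnot(inherits(config, "dgp_config"), R >= 2)
  if (is.null(base_seed)) base_seed <- config$seed
  truth_vals <- if (is.null(truth)) {
    c(cluster_ratio = 1, individual_ratio = 1, geometric_ratio = 1)
  } else {
    stopifnot(inherits(truth, "crt_truth"))
    c(cluster_ratio = truth$cluster_ratio,
      individual_ratio = truth$individual_ratio,
      geometric_ratio = truth$geometric_ratio)
  }
  K <- length(estimators)
  nm <- vapply(estimators, `[[`, "", "name")
  est <- se <- lo <- hi <- pv <- matrix(NA_real_, R, K, dimnames = list(NULL, nm))
  sel_out <- sel_ps <- matrix(NA_character_, R, K, dimnames = list(NULL, nm))
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- base_seed + r
    data <- simulate_crt(cfg)
    for (k in seq_len(K)) {
      fit <- tryCatch(suppressWarnings(estimators[[k]]$fn(data)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      est[r, k] <- fit$estimate
      se[r, k] <- fit$se
      lo[r, k] <- fit$ci_lo; hi[r, k] <- fit$ci_hi
      pv[r, k] <- fit$p_value
      if (!is.null(fit$selection)) {
        sel_out[r, k] <- fit$selection$outcome_label
        sel_ps[r, k] <- fit$selection$ps_label
      }
    }
  }
  rows <- lapply(seq_len(K), function(k) {
    tr <- truth_vals[[estimators[[k]]$truth]]
    ok <- !is.na(est[, k])
    data.frame(
      estimator = nm[k], target = estimators[[k]]$truth, truth = tr,
      pt = mean(est[ok, k]), bias = mean(est[ok, k]) - tr,
      sigma = stats::sd(log(est[ok, k])), sigma_hat = mean(se[ok, k]),
      coverage = mean(lo[ok, k] <= tr & tr <= hi[ok, k]),
      reject = mean(pv[ok, k] < alpha_level, na.rm = TRUE),
      n_used = sum(ok), n_fail = sum(!ok),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("crt_sim_summary", "data.frame")
  attr(out, "selections") <- list(outcome = sel_out, propensity = sel_ps)
  attr(out, "R") <- R
  attr(out, "base_seed") <- base_seed
  out
}

#' Adaptive Prespecification selection frequencies across replicates
#'
#' Tabulates, for an adaptive estimator run through [run_study()], the
#' share of replicates in which each candidate adjustment set was selected.
#'
#' @param x A `crt_sim_summary` from [run_study()], or a character vector
#'   of selection labels.
#' @param estimator Name of the estimator column (required when `x` is a
#'   summary containing several).
#' @param stage `"outcome"` or `"propensity"`.
#' @return A named numeric vector of selection proportions (summing to 1
#'   over replicates where the estimator succeeded), sorted decreasingly.
#' @export
selection_frequencies <- function(x, estimator = NULL,
                                  stage = c("outcome", "propensity")) {
  stage <- match.arg(stage)
  labels <- if (is.character(x)) {
    x
  } else {
    sel <- attr(x, "selections")[[stage]]
    if (is.null(sel)) stop("no selection records in this summary")
    if (is.null(estimator)) {
      if (ncol(sel) == 1) estimator <- colnames(sel)[1] else
        stop("several estimators present; name one")
    }
    sel[, estimator]
  }
  labels <- labels[!is.na(labels)]
  if (!length(labels)) stop("no replicates with a recorded selection")
  tab <- sort(table(labels) / length(labels), decreasing = TRUE)
  stats::setNames(as.numeric(tab), names(tab))
}

#' @export
print.crt_sim_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation summary over %d replicates (base seed %d):\n",
              attr(x, "R"), attr(x, "base_seed")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
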