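# Adaptive Prespecification: data-adaptive selection among prespecified
# candidate adjustment regressions, by cross-validated variance of the
# estimated influence function. Selection is deterministic given the data:
# folds are defined by cluster (or pair) identity, never by random splits.

.cand_label <- function(adj) {
  if (!length(adj)) "(unadjusted)" else paste(adj, collapse = "+")
}

# Order candidates toward parsimony: fewer covariates first, then
# lexicographic on the sorted covariate names. which.min() then breaks CV
# ties toward the smaller adjustment set.
.cand_order <- function(cands) {
  key <- vapply(cands, function(a) {
    sprintf("%03d|%s", length(a), paste(sort(a), collapse = "+"))
  }, "")
  order(key)
}

# Mean over folds of the squared held-out influence-function contribution
# for the contrast (log-ratio scale for ratio estimands). `engine` fits the
# candidate on a training set and returns psi and per-cluster IF values for
# all clusters. Returns NA if the candidate fails on any training fold.
.ap_cv_var <- function(engine, outcome_adj, ps_adj, folds, scale) {
  J <- sum(lengths(folds))
  loss <- numeric(length(folds))
  for (k in seq_along(folds)) {
    hold <- folds[[k]]
    fit <- tryCatch(
      engine(outcome_adj, ps_adj, setdiff(seq_len(J), hold)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    d1 <- mean(fit$D1[hold]); d0 <- mean(fit$D0[hold])
    d <- if (scale == "ratio") {
      if (fit$psi1 <= 0 || fit$psi0 <= 0) return(NA_real_)
      d1 / fit$psi1 - d0 / fit$psi0
    } else {
      d1 - d0
    }
    loss[k] <- d^2
  }
  mean(loss)
}

.ap_folds <- function(data, cv) {
  if (cv == "pair") {
    pid <- data$clusters$pair_id
    if (anyNA(pid)) stop("leave-one-pair-out CV requires pair ids")
    unname(split(seq_len(data$J), pid))
  } else {
    as.list(seq_len(data$J))
  }
}

#' TMLE with Adaptive Prespecification
#'
#' Selects, among prespecified candidate generalized linear adjustment
#' regressions, the combination that maximizes empirical efficiency, then
#' refits the chosen TMLE on the full data. Selection proceeds in two
#' stages with the squared influence function of the target contrast as
#' loss, cross-validated by leaving one cluster (or one matched pair, when
#' pairs are kept) out:
#' \enumerate{
#'   \item each candidate outcome regression is scored with the propensity
#'     fixed at its known design value 0.5; the minimizer is kept;
#'   \item holding that outcome regression, each candidate propensity
#'     regression is scored; the minimizer is kept.
#' }
#' Ties are broken toward the smaller adjustment set, then lexicographic
#' covariate name. The unadjusted candidate (empty set) is always included,
#' so adaptive selection can never be forced into harmful adjustment.
#' Candidates whose fit fails on any training fold are excluded with a
#' warning.
#'
#' @inheritParams cluster_tmle
#' @param estimator Which TMLE to select for: `"cluster_tmle"` (cluster-level
#'   candidates, e.g. `W1c`, `E1`), `"hierarchical_tmle"` or `"hybrid_tmle"`
#'   (individual-level outcome candidates).
#' @param outcome_candidates List of character vectors of adjustment sets
#'   for the outcome regression. Defaults to the unadjusted set plus each
#'   available covariate singly (`W*c` for the cluster-level TMLE, `W*` for
#'   the individual-level ones).
#' @param ps_candidates List of candidate propensity adjustment sets; the
#'   empty set (known 0.5) is always included. Defaults to
#'   `outcome_candidates` (for the hybrid TMLE, to their cluster-level
#'   `W*c` counterparts).
#' @param cv `"cluster"` for leave-one-cluster-out or `"pair"` for
#'   leave-one-pair-out; default follows `estimand$matching`.
#' @return A `crt_effect` object whose `selection` element records the
#'   chosen adjustment sets and the per-candidate cross-validated variance
#'   estimates (`outcome_cv`, `ps_cv`).
#' @export
adaptive_prespec <- function(data, estimand = estimand_spec(),
                             estimator = c("cluster_tmle",
                                           "hierarchical_tmle",
                                           "hybrid_tmle"),
                             outcome_candidates = NULL,
                             ps_candidates = NULL,
                             cv = NULL, conf_level = 0.95) {
  stopifnot(inherits(data, "crt_data"), inherits(estimand, "estimand_spec"))
  estimator <- match.arg(estimator)
  if (is.null(cv)) cv <- if (estimand$matching == "keep") "pair" else "cluster"
  cv <- match.arg(cv, c("cluster", "pair"))
  .check_binary_outcome(data)

  cl_level <- estimator == "cluster_tmle"
  if (is.null(outcome_candidates)) {
    vars <- if (cl_level) paste0(data$w_names, "c") else data$w_names
    outcome_candidates <- c(list(character()), lapply(vars, identity))
  }
  if (is.null(ps_candidates)) {
    ps_candidates <- if (estimator == "hybrid_tmle") {
      lapply(outcome_candidates, function(a) if (length(a)) paste0(a, "c") else a)
    } else {
      outcome_candidates
    }
  }
  if (!any(lengths(outcome_candidates) == 0)) {
    outcome_candidates <- c(list(character()), outcome_candidates)
  }
  if (!any(lengths(ps_candidates) == 0)) {
    ps_candidates <- c(list(character()), ps_candidates)
  }

  avail <- if (cl_level) names(data$clusters) else names(data$individuals)
  bad <- setdiff(unique(unlist(c(outcome_candidates,
                                 if (!cl_level && estimator == "hybrid_tmle")
                                   NULL else ps_candidates))), avail)
  if (estimator == "hybrid_tmle") {
    bad <- c(bad, setdiff(unique(unlist(ps_candidates)),
                          names(data$clusters)))
  }
  if (length(bad)) {
    stop("candidate covariates not found in the data: ",
         paste(unique(bad), collapse = ", "))
  }

  w <- analysis_weights(data, estimand$level)
  engine <- switch(estimator,
    cluster_tmle = function(o, p, train) {
      .ctmle_fit(data$clusters, w, o, p, train = train, quiet = TRUE)
    },
    hierarchical_tmle = function(o, p, train) {
      .htmle_fit(data, estimand$level, o, p, train = train, quiet = TRUE)
    },
    hybrid_tmle = function(o, p, train) {
      init <- .aggregate_init(data, o, train = train, quiet = TRUE)
      .ctmle_fit(data$clusters, w, character(), p, train = train,
                 init = init, quiet = TRUE)
    })
  folds <- .ap_folds(data, cv)

  score_stage <- function(cands, fixed_outcome = NULL) {
    cands <- cands[.cand_order(cands)]
    cvv <- vapply(cands, function(cand) {
      if (is.null(fixed_outcome)) {
        .ap_cv_var(engine, cand, character(), folds, estimand$scale)
      } else {
        .ap_cv_var(engine, fixed_outcome, cand, folds, estimand$scale)
      }
    }, 0)
    names(cvv) <- vapply(cands, .cand_label, "")
    if (anyNA(cvv)) {
      warning("candidate(s) excluded after failing on a training fold: ",
              paste(names(cvv)[is.na(cvv)], collapse = ", "))
    }
    if (all(is.na(cvv))) stop("every candidate failed during cross-validation")
    list(cands = cands, cv = cvv, pick = cands[[which.min(cvv)]])
  }

  s1 <- score_stage(outcome_candidates)
  s2 <- score_stage(ps_candidates, fixed_outcome = s1$pick)

  fit_fun <- switch(estimator, cluster_tmle = cluster_tmle,
                    hierarchical_tmle = hierarchical_tmle,
                    hybrid_tmle = hybrid_tmle)
  est <- fit_fun(data, estimand, outcome_adj = s1$pick, ps_adj = s2$pick,
                 conf_level = conf_level)
  est$estimator <- paste(est$estimator, "(Adaptive Prespecification)")
  est$selection <- list(outcome = s1$pick, propensity = s2$pick,
                        outcome_label = .cand_label(s1$pick),
                        ps_label = .cand_label(s2$pick),
                        outcome_cv = s1$cv, ps_cv = s2$cv, cv = cv)
  est
}
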