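#' Construct a cluster randomized trial data object
#'
#' Bundles individual-level records from a two-arm cluster randomized trial
#' (CRT) together with their cluster-level aggregates. Covariate columns are
#' classified by name: columns starting with `"E"` are cluster-level
#' covariates (must be constant within each cluster), columns starting with
#' `"W"` are individual-level covariates. For every individual-level
#' covariate `W*`, the cluster-level empirical mean is computed and exposed
#' as `W*c` (e.g. `W1` gives `W1c`) so that cluster-level regressions can
#' adjust for summaries of individual-level information.
#'
#' @param individuals A data.frame with one row per participant and columns
#'   `cluster_id`, `A` (arm indicator, 0/1), `Y` (binary outcome), optionally
#'   `pair_id`, plus covariate columns named `W*` (individual-level) or `E*`
#'   (cluster-level).
#' @param alpha Optional numeric vector of aggregation weights
#'   \eqn{\alpha_{ij}}, one per row of `individuals`. The cluster-level
#'   outcome is \eqn{Y^c_j = \sum_i \alpha_{ij} Y_{ij}}. Defaults to
#'   \eqn{1/N_j} (within-cluster mean), under which \eqn{Y^c_j} is the
#'   cluster's empirical outcome proportion.
#'
#' @return An object of class `crt_data`: a list with elements
#'   `individuals`, `clusters` (one row per cluster with `cluster_id`,
#'   `pair_id`, `A`, `N`, `Yc`, the `E*` covariates and the `W*c` means),
#'   `J`, `NT`, `alpha`, `w_names`, `e_names`, and `cluster_only = FALSE`.
#' @seealso [crt_data_clusters()] for trials where only cluster-level data
#'   are available, [validate_crt()], [read_individual_csv()].
#' @examples
#' d <- data.frame(cluster_id = rep(1:4, each = 3),
#'                 A = rep(c(1, 0), each = 6),
#'                 Y = rbinom(12, 1, 0.3),
#'                 W1 = rnorm(12), E1 = rep(rnorm(4), each = 3))
#' x <- crt_data(d)
#' x$clusters
#' @export
crt_data <- function(individuals, alpha = NULL) {
  stopifnot(is.data.frame(individuals))
  required <- c("cluster_id", "A", "Y")
  missing_cols <- setdiff(required, names(individuals))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  individuals$cluster_id <- as.character(individuals$cluster_id)
  if (!"pair_id" %in% names(individuals)) individuals$pair_id <- NA_character_
  individuals$pair_id <- as.character(individuals$pair_id)

  covar_cols <- setdiff(names(individuals), c(required, "pair_id"))
  e_names <- covar_cols[startsWith(covar_cols, "E")]
  w_names <- covar_cols[startsWith(covar_cols, "W")]
  unknown <- setdiff(covar_cols, c(e_names, w_names))
  if (length(unknown)) {
    stop("covariate columns must be named W* (individual-level) or E* ",
         "(cluster-level); offending: ", paste(unknown, collapse = ", "))
  }

  cid <- factor(individuals$cluster_id, levels = unique(individuals$cluster_id))
  n_j <- as.integer(table(cid))
  if (is.null(alpha)) alpha <- 1 / n_j[as.integer(cid)]
  if (length(alpha) != nrow(individuals) || anyNA(alpha) || any(alpha < 0)) {
    bad <- which(is.na(alpha) | alpha < 0)
    stop("alpha must be a non-negative weight for every individual",
         if (length(bad)) paste0("; first offending row: ", bad[1]))
  }

  first_of <- function(v) v[!duplicated(cid)]
  clusters <- data.frame(
    cluster_id = levels(cid),
    pair_id = first_of(individuals$pair_id),
    A = first_of(individuals$A),
    N = n_j,
    Yc = as.numeric(rowsum(alpha * individuals$Y, cid)),
    stringsAsFactors = FALSE
  )
  for (e in e_names) clusters[[e]] <- first_of(individuals[[e]])
  for (w in w_names) {
    clusters[[paste0(w, "c")]] <- as.numeric(rowsum(individuals[[w]], cid)) / n_j
  }

  structure(list(
    individuals = individuals,
    clusters = clusters,
    J = nrow(clusters),
    NT = nrow(individuals),
    alpha = alpha,
    w_names = w_names,
    e_names = e_names,
    cluster_only = FALSE
  ), class = "crt_data")
}

#' Construct a CRT data object from cluster-level records only
#'
#' For trials where individual rows are unavailable, estimation can proceed
#' from cluster-level aggregates alone (cluster-level estimators, with
#' weights to target individual-level effects).
#'
#' @param clusters A data.frame with one row per cluster and columns
#'   `cluster_id`, `A`, `Yc` (aggregated outcome in \[0, 1\]), `N` (cluster
#'   size), optionally `pair_id`, plus cluster-level covariates `E*` (and,
#'   if available, `W*c` means).
#' @return A `crt_data` object with `cluster_only = TRUE` and no
#'   `individuals` element. Estimators that require individual-level rows
#'   (hierarchical/hybrid TMLE, CARE, GEE) refuse such objects.
#' @export
crt_data_clusters <- function(clusters) {
  stopifnot(is.data.frame(clusters))
  required <- c("cluster_id", "A", "Yc", "N")
  missing_cols <- setdiff(required, names(clusters))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(clusters$Yc < 0 | clusters$Yc > 1)) {
    stop("Yc must lie in [0, 1]; offending clusters: ",
         paste(clusters$cluster_id[clusters$Yc < 0 | clusters$Yc > 1],
               collapse = ", "))
  }
  clusters$cluster_id <- as.character(clusters$cluster_id)
  if (!"pair_id" %in% names(clusters)) clusters$pair_id <- NA_character_
  covar_cols <- setdiff(names(clusters), c(required, "pair_id"))
  e_names <- covar_cols[startsWith(covar_cols, "E")]
  structure(list(
    individuals = NULL,
    clusters = clusters,
    J = nrow(clusters),
    NT = sum(clusters$N),
    alpha = NULL,
    w_names = character(),
    e_names = e_names,
    cluster_only = TRUE
  ), class = "crt_data")
}

#' @export
print.crt_data <- function(x, ...) {
  cat("Cluster randomized trial data:", x$J, "clusters,",
      x$NT, "participants\n")
  cat("  arms: A=1 in", sum(x$clusters$A == 1), "clusters, A=0 in",
      sum(x$clusters$A == 0), "clusters\n")
  if (any(!is.na(x$clusters$pair_id))) {
    cat("  matched pairs:", length(unique(stats::na.omit(x$clusters$pair_id))), "\n")
  }
  cat("  cluster sizes:", paste(range(x$clusters$N), collapse = "-"), "\n")
  if (length(x$e_names)) cat("  cluster covariates:", paste(x$e_names, collapse = ", "), "\n")
  if (length(x$w_names)) cat("  individual covariates:", paste(x$w_names, collapse = ", "), "\n")
  if (x$cluster_only) cat("  (cluster-level records only)\n")
  invisible(x)
}

#' Aggregate individual outcomes to a cluster-level outcome
#'
#' Computes the weighted sum \eqn{\sum_i \alpha_i y_i}. With the default
#' weights \eqn{\alpha_i = 1/N} this is the cluster's empirical outcome
#' proportion.
#'
#' @param y Numeric outcome vector for one cluster.
#' @param alpha Aggregation weights, one per individual; default `1/length(y)`.
#' @return A single number, in \[0, 1\] for binary outcomes under default
#'   weights.
#' @export
aggregate_outcome <- function(y, alpha = NULL) {
  if (is.null(alpha)) alpha <- rep(1 / length(y), length(y))
  if (length(alpha) != length(y)) {
    stop("need one weight per individual (", length(y), "), got ", length(alpha))
  }
  if (anyNA(alpha)) {
    stop("missing weight for individual(s) ",
         paste(which(is.na(alpha)), collapse = ", "))
  }
  sum(alpha * y)
}

#' Pooled individual-level mean outcome within an arm
#'
#' The arm-specific empirical mean giving equal weight to every participant:
#' \eqn{\sum_{j: A_j=a} \sum_i Y_{ij} / \sum_{j: A_j=a} N_j}.
#'
#' @param data A `crt_data` object.
#' @param arm Arm indicator, 0 or 1.
#' @return A single proportion.
#' @export
pooled_individual_mean <- function(data, arm) {
  stopifnot(inherits(data, "crt_data"))
  cl <- data$clusters
  in_arm <- cl$A == arm
  if (!any(in_arm)) stop("no clusters in arm ", arm)
  if (data$cluster_only) {
    return(sum(cl$N[in_arm] * cl$Yc[in_arm]) / sum(cl$N[in_arm]))
  }
  ind <- data$individuals
  rows <- ind$A == arm
  mean(ind$Y[rows])
}

#' Per-cluster analysis weights for a target level
#'
#' The cluster-level analysis of a CRT uses one weight per cluster,
#' \eqn{J/N_T \times 1/\alpha_{ij}}: under equal aggregation weights
#' \eqn{\alpha_{ij} = 1/N_j} this is \eqn{J N_j / N_T} when targeting the
#' individual-level effect (each participant counts equally) and 1 when
#' targeting the cluster-level effect (each cluster counts equally). Weights
#' are normalized to sum to \eqn{J}.
#'
#' @param data A `crt_data` object.
#' @param target `"cluster"` or `"individual"`.
#' @return Numeric vector of length `J`, aligned with `data$clusters`.
#' @export
analysis_weights <- function(data, target = c("cluster", "individual")) {
  stopifnot(inherits(data, "crt_data"))
  target <- match.arg(target)
  if (target == "cluster") return(rep(1, data$J))
  if (data$cluster_only || is.null(data$alpha)) {
    w <- data$J * data$clusters$N / data$NT
    return(w)
  }
  cid <- factor(data$individuals$cluster_id, levels = data$clusters$cluster_id)
  a_j <- tapply(data$alpha, cid, function(a) {
    if (max(a) - min(a) > 1e-12 * max(abs(a), 1)) {
      stop("analysis weights are only defined when alpha is constant ",
           "within each cluster")
    }
    a[1]
  })
  w <- (data$J / data$NT) / as.numeric(a_j)
  data$J * w / sum(w)
}

#' Check CRT data invariants
#'
#' Reports (never throws) every violation of the CRT data invariants:
#' at least 4 clusters, both arms non-empty, binary arm and outcome,
#' pair ids shared by exactly two clusters with opposite arms, and
#' cluster-level covariates constant within cluster.
#'
#' @param data A `crt_data` object.
#' @return Character vector of violation messages; empty if the data are
#'   valid.
#' @export
validate_crt <- function(data) {
  stopifnot(inherits(data, "crt_data"))
  v <- character()
  cl <- data$clusters
  if (data$J < 4) v <- c(v, sprintf("only %d clusters (need >= 4)", data$J))
  if (!all(cl$A %in% c(0, 1))) {
    v <- c(v, paste0("non-binary arm indicator in clusters: ",
                     paste(cl$cluster_id[!cl$A %in% c(0, 1)], collapse = ", ")))
  } else if (length(unique(cl$A)) < 2) {
    v <- c(v, sprintf("all clusters in arm %s", unique(cl$A)))
  }
  if (!data$cluster_only) {
    ind <- data$individuals
    if (!all(ind$Y %in% c(0, 1))) {
      bad <- unique(ind$cluster_id[!ind$Y %in% c(0, 1)])
      v <- c(v, paste0("non-binary outcome in clusters: ",
                       paste(bad, collapse = ", ")))
    }
    cid <- factor(ind$cluster_id, levels = cl$cluster_id)
    n_j <- as.integer(table(cid))
    if (any(n_j != cl$N)) {
      bad <- cl$cluster_id[n_j != cl$N]
      v <- c(v, paste0("cluster size mismatch in clusters: ",
                       paste(bad, collapse = ", ")))
    }
    for (e in data$e_names) {
      n_distinct <- tapply(ind[[e]], cid, function(x) length(unique(x)))
      if (any(n_distinct > 1)) {
        v <- c(v, paste0(e, " not constant within clusters: ",
                         paste(cl$cluster_id[n_distinct > 1], collapse = ", ")))
      }
    }
    arm_by_cl <- tapply(ind$A, cid, function(x) length(unique(x)))
    if (any(arm_by_cl > 1)) {
      v <- c(v, paste0("arm indicator not constant within clusters: ",
                       paste(cl$cluster_id[arm_by_cl > 1], collapse = ", ")))
    }
  }
  pid <- cl$pair_id[!is.na(cl$pair_id)]
  if (length(pid)) {
    sizes <- table(cl$pair_id[!is.na(cl$pair_id)])
    if (any(sizes != 2)) {
      v <- c(v, paste0("pair ids not shared by exactly 2 clusters: ",
                       paste(names(sizes)[sizes != 2], collapse = ", ")))
    }
    for (p in names(sizes)[sizes == 2]) {
      arms <- cl$A[!is.na(cl$pair_id) & cl$pair_id == p]
      if (length(unique(arms)) != 2) {
        v <- c(v, paste0("pair ", p, " does not contain opposite arms"))
      }
    }
  }
  if (data$NT != sum(cl$N)) {
    v <- c(v, sprintf("total size mismatch: NT = %d but sum(Nj) = %d",
                      data$NT, sum(cl$N)))
  }
  v
}

#' Specify the target estimand of a CRT analysis
#'
#' @param level Target level of the effect: `"cluster"` (each cluster
#'   weighted equally) or `"individual"` (each participant weighted
#'   equally). Under informative cluster size the two can differ
#'   substantially.
#' @param scale Contrast scale: `"ratio"` (relative effect
#'   \eqn{\psi(1)/\psi(0)}, inference on the log scale) or `"difference"`.
#' @param matching `"break"` to analyze clusters as independent units, or
#'   `"keep"` to treat matched pairs as the independent unit (requires
#'   `pair_id`).
#' @return An object of class `estimand_spec`.
#' @export
estimand_spec <- function(level = c("cluster", "individual"),
                          scale = c("ratio", "difference"),
                          matching = c("break", "keep")) {
  structure(list(level = match.arg(level), scale = match.arg(scale),
                 matching = match.arg(matching)),
            class = "estimand_spec")
}

#' @export
print.estimand_spec <- function(x, ...) {
  cat(sprintf("CRT estimand: %s-level effect, %s scale, %sing matched pairs\n",
              x$level, x$scale, x$matching))
  invisible(x)
}
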