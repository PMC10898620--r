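# Generalized estimating equations for the individual-level relative effect,
# with a hand-rolled solver: log link, Poisson variance function (relative
# risk regression for a binary outcome), independence or exchangeable
# working correlation, robust sandwich variance with the Fay-Graubard
# small-sample correction. Solved directly since no GEE package is among
# the package's dependencies.

# Per-cluster pieces of the estimating equation
#   sum_j D_j' V_j^{-1} (Y_j - mu_j) = 0,  D_j = diag(mu_j) X_j.
# For the exchangeable inverse the rank-one form
#   R^{-1} = 1/(1-rho) [I - rho/(1+(n-1)rho) 11']
# avoids materializing V_j.
.gee_pieces <- function(X, y, mu, cid, rho = 0) {
  # returns A = sum D'V^-1 D, U = matrix of per-cluster scores (p x J),
  # using var(mu) = mu (Poisson variance function), phi fixed at 1.
  p <- ncol(X)
  J <- nlevels(cid)
  # D'V^{-1} rows: for independence, D'V^-1 = X' diag(mu) diag(1/mu) = X'.
  if (rho == 0) {
    # D'V^{-1}(y - mu) = X'(y - mu); D'V^{-1}D = X' diag(mu) X
    U <- t(rowsum(X * (y - mu), cid))
    A <- crossprod(X, X * mu)
    Alist <- lapply(seq_len(J), function(j) {
      rows <- which(as.integer(cid) == j)
      crossprod(X[rows, , drop = FALSE], X[rows, , drop = FALSE] * mu[rows])
    })
  } else {
    s <- sqrt(mu)
    U <- matrix(0, p, J)
    A <- matrix(0, p, p)
    Alist <- vector("list", J)
    idx <- split(seq_along(y), cid)
    for (j in seq_len(J)) {
      rows <- idx[[j]]
      n <- length(rows)
      c1 <- 1 / (1 - rho)
      c2 <- rho / ((1 - rho) * (1 + (n - 1) * rho))
      # D'V^{-1} = X' diag(mu) diag(1/s) R^{-1} diag(1/s) = X' diag(s) R^{-1} diag(1/s)
      Xs <- X[rows, , drop = FALSE] * s[rows]          # X' diag(s)
      r <- (y[rows] - mu[rows]) / s[rows]
      U[, j] <- c1 * crossprod(Xs, r) - c2 * colSums(Xs) * sum(r)
      # D'V^{-1} D = X' diag(s) R^{-1} diag(s) X
      Aj <- c1 * crossprod(Xs) - c2 * tcrossprod(colSums(Xs))
      Alist[[j]] <- Aj
      A <- A + Aj
    }
  }
  list(A = A, U = U, Alist = Alist)
}

.fg_sandwich <- function(A, U, Alist, b = 0.75) {
  # Fay-Graubard small-sample correction: inflate each cluster's score by
  # diag{(1 - min(b, h_jii))^(-1/2)} with H_j = A_j A^{-1}, then sandwich.
  Ainv <- solve(A)
  p <- nrow(A)
  meat <- matrix(0, p, p)
  infl <- matrix(0, p, ncol(U))
  for (j in seq_len(ncol(U))) {
    h <- pmin(pmax(diag(Alist[[j]] %*% Ainv), 0), b)
    g <- 1 / sqrt(1 - h)
    infl[, j] <- g
    u <- g * U[, j]
    meat <- meat + tcrossprod(u)
  }
  list(vcov = Ainv %*% meat %*% Ainv, inflation = infl)
}

#' Log-link GEE for the individual-level relative effect
#'
#' Solves the generalized estimating equation for the marginal (or
#' covariate-conditional) model \eqn{\mu(A) = \exp(\beta_0 + \beta_A A +
#' \beta_W' W)} on pooled individual rows, with the Poisson variance
#' function (relative risk regression for a binary outcome) and the chosen
#' working correlation. \eqn{e^{\beta_A}} is the relative effect. The
#' variance of \eqn{\hat\beta_A} is the robust sandwich with the
#' Fay-Graubard small-sample inflation of each cluster's score
#' contribution; the Wald test uses a t reference with `J - 2` degrees of
#' freedom. With an independence working correlation and no covariates the
#' point estimate equals the ratio of pooled arm means exactly. Weighted
#' GEE targeting cluster-level effects is deliberately not offered: the
#' appropriate weighting is not established and can introduce bias.
#'
#' @param data A [crt_data] object with individual-level records.
#' @param adjustment Character vector of adjustment covariates (the
#'   conditional model); empty fits the marginal model. Note that with a
#'   log link and covariates the treatment coefficient retains a relative
#'   interpretation only under no interaction.
#' @param corstr Working correlation: `"independence"` (default) or
#'   `"exchangeable"`.
#' @param conf_level Confidence level.
#' @param maxit,tol Newton iteration controls.
#' @return An object of class `crt_gee` with elements `coefficients`,
#'   `vcov` (corrected sandwich), `estimate` (\eqn{e^{\beta_A}}), `se`
#'   (log scale), `ci_lo`, `ci_hi`, `statistic`, `df`, `p_value`, `rho`,
#'   `corstr`, `iterations`, and `fg_inflation` (per-cluster correction
#'   factors, all at least 1).
#' @export
crt_gee <- function(data, adjustment = character(),
                    corstr = c("independence", "exchangeable"),
                    conf_level = 0.95, maxit = 50, tol = 1e-10) {
  stopifnot(inherits(data, "crt_data"))
  if (data$cluster_only) stop("GEE requires individual-level records")
  corstr <- match.arg(corstr)
  ind <- data$individuals
  cid <- factor(ind$cluster_id, levels = data$clusters$cluster_id)
  X <- .design(ind, adjustment)
  y <- ind$Y
  p <- ncol(X)

  # independence solution (= log-link quasi-Poisson GLM score) as start
  beta <- c(log(max(mean(y), 1e-6)), rep(0, p - 1))
  rho <- 0
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    pieces <- .gee_pieces(X, y, mu, cid, rho = rho)
    S <- rowSums(pieces$U)
    step <- tryCatch(solve(pieces$A, S), error = function(e) NULL)
    if (is.null(step)) stop("GEE update failed (singular working information)")
    beta <- beta + step
    trace <- c(trace, sqrt(sum(S^2)))
    converged <- sqrt(sum(step^2)) < tol
    if (corstr == "exchangeable") {
      mu <- exp(drop(X %*% beta))
      r <- (y - mu) / sqrt(mu)
      phi <- sum(r^2) / (length(y) - p)
      num <- sum(tapply(r, cid, function(z) (sum(z)^2 - sum(z^2)) / 2))
      den <- sum(tapply(r, cid, function(z) length(z) * (length(z) - 1) / 2))
      rho_new <- (num / den) / phi
      rho_new <- max(min(rho_new, 0.95), 0)
      if (converged && abs(rho_new - rho) < 1e-8) {rho <- rho_new; break}
      rho <- rho_new
    } else if (converged) break
    if (it == maxit) {
      stop("GEE did not converge in ", maxit, " iterations; score norms: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
    }
  }

  mu <- exp(drop(X %*% beta))
  pieces <- .gee_pieces(X, y, mu, cid, rho = rho)
  sw <- .fg_sandwich(pieces$A, pieces$U, pieces$Alist)
  se <- sqrt(diag(sw$vcov))
  names(beta) <- names(se) <- colnames(X)
  .gee_result(beta, sw, se, data$J, conf_level, corstr, rho, it,
              estimator = "GEE")
}

.gee_result <- function(beta, sw, se, J, conf_level, corstr, rho, it,
                        estimator) {
  df <- J - 2
  bA <- beta[["A"]]; seA <- se[["A"]]
  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(
    estimator = estimator,
    coefficients = beta, vcov = sw$vcov, se_coef = se,
    estimate = exp(bA), se = seA,
    ci_lo = exp(bA - tc * seA), ci_hi = exp(bA + tc * seA),
    statistic = bA / seA, df = df,
    p_value = 2 * stats::pt(-abs(bA / seA), df),
    corstr = corstr, rho = rho, iterations = it,
    fg_inflation = sw$inflation,
    level = "individual", scale = "ratio"
  ), class = "crt_gee")
}

#' @export
print.crt_gee <- function(x, digits = 4, ...) {
  cat(x$estimator, "(log link,", x$corstr, "working correlation)\n")
  if (x$corstr == "exchangeable") {
    cat(sprintf("  working correlation rho = %.*g\n", digits, x$rho))
  }
  coefs <- cbind(Estimate = x$coefficients, `Robust SE` = x$se_coef)
  print(round(coefs, digits))
  cat(sprintf("  relative effect exp(bA) = %.*g  (95%% CI %.*g to %.*g)\n",
              digits, x$estimate, digits, x$ci_lo, digits, x$ci_hi))
  cat(sprintf("  t = %.*g on %g df, p = %.*g\n",
              digits, x$statistic, x$df, digits, x$p_value))
  invisible(x)
}

#' Augmented GEE for the marginal relative effect
#'
#' Solves the augmented estimating equation: the marginal log-link GEE
#' score minus \eqn{\sum_a [1(A_j = a) - \pi^c(a)]\, \gamma_a} with
#' \eqn{\gamma_a = D_j(a)' V_j^{-1} (\hat\mu(a, E_j, W_{ij}) - \mu(a))},
#' which restores the marginal interpretation of \eqn{e^{\beta_A}} while
#' adjusting for covariates. The cluster-level propensity is treated as
#' known (0.5). Conditional outcome predictions come from a pooled logistic
#' regression of the outcome on arm and the adjustment covariates,
#' evaluated at both arms. Independence working correlation; variance as in
#' [crt_gee()] with the augmented per-cluster scores.
#'
#' @inheritParams crt_gee
#' @param pi1 Known allocation probability (default 0.5).
#' @return An object of class `crt_gee`.
#' @export
aug_gee <- function(data, adjustment = character(), pi1 = 0.5,
                    conf_level = 0.95, maxit = 50, tol = 1e-10) {
  stopifnot(inherits(data, "crt_data"))
  if (data$cluster_only) stop("augmented GEE requires individual-level records")
  ind <- data$individuals
  cl <- data$clusters
  cid <- factor(ind$cluster_id, levels = cl$cluster_id)
  y <- ind$Y
  J <- data$J
  n_j <- as.integer(table(cid))

  # conditional outcome regression (logit link, includes the arm)
  Xq <- .design(ind, adjustment)
  bq <- .glm_try(Xq, y)
  if (is.null(bq)) stop("conditional outcome regression failed")
  X1 <- Xq; X1[, "A"] <- 1
  X0 <- Xq; X0[, "A"] <- 0
  q1 <- stats::plogis(drop(X1 %*% bq))
  q0 <- stats::plogis(drop(X0 %*% bq))
  q1_j <- as.numeric(rowsum(q1, cid))   # sums of conditional predictions
  q0_j <- as.numeric(rowsum(q0, cid))

  # marginal model pieces: x_i(a) = (1, a); independence, Poisson variance,
  # so D'V^{-1} collapses to the design row itself.
  A_j <- cl$A
  w1 <- (A_j == 1) - pi1        # 1(A=a) - pi(a), a = 1
  w0 <- (A_j == 0) - (1 - pi1)  # a = 0
  score <- function(beta) {
    m1 <- exp(beta[1] + beta[2]); m0 <- exp(beta[1])
    m_j <- ifelse(A_j == 1, m1, m0)
    d_j <- as.numeric(rowsum(y, cid))
    # GEE part per cluster: sum_i (1, A_j)'(y - m_Aj)
    g0 <- d_j - n_j * m_j               # intercept row
    g1 <- ifelse(A_j == 1, g0, 0)       # A row
    # augmentation gamma_a per cluster: sum_i (1, a)'(q_a - m_a)
    a0_1 <- q1_j - n_j * m1             # a = 1, both rows (second row equal)
    a0_0 <- q0_j - n_j * m0             # a = 0, second row 0
    U <- rbind(g0 - (w1 * a0_1 + w0 * a0_0),
               g1 - w1 * a0_1)
    list(S = rowSums(U), U = U, m1 = m1, m0 = m0, m_j = m_j)
  }
  jacobian <- function(beta) {
    m1 <- exp(beta[1] + beta[2]); m0 <- exp(beta[1])
    m_j <- ifelse(A_j == 1, m1, m0)
    # d/dbeta of GEE part: -sum_j sum_i m_Aj x x'
    Jg <- -matrix(c(sum(n_j * m_j), sum(n_j * m_j * A_j),
                    sum(n_j * m_j * A_j), sum(n_j * m_j * A_j)), 2, 2)
    # d/dbeta of -sum_a w_a gamma_a:  + sum_j [w1 m1 n_j (1,1)'(1,1)
    #                                         + w0 m0 n_j (1,0)'(1,0)]
    c11 <- sum(w1 * n_j * m1); c00 <- sum(w0 * n_j * m0)
    Ja <- matrix(c(c11 + c00, c11, c11, c11), 2, 2)
    Jg + Ja
  }

  start <- crt_gee(data, adjustment = character(), maxit = maxit, tol = tol)
  beta <- unname(start$coefficients[c("(Intercept)", "A")])
  for (it in seq_len(maxit)) {
    sc <- score(beta)
    step <- tryCatch(solve(jacobian(beta), -sc$S), error = function(e) NULL)
    if (is.null(step)) stop("augmented GEE update failed (singular Jacobian)")
    beta <- beta + step
    if (sqrt(sum(step^2)) < tol) break
    if (it == maxit) {
      stop("augmented GEE did not converge in ", maxit, " iterations; ",
           "last score norm: ", signif(sqrt(sum(sc$S^2)), 3))
    }
  }

  sc <- score(beta)
  # bread: sum_j D'V^{-1}D of the marginal model
  Alist <- lapply(seq_len(J), function(j) {
    m <- sc$m_j[j]; a <- A_j[j]
    n_j[j] * m * matrix(c(1, a, a, a), 2, 2)
  })
  A <- Reduce(`+`, Alist)
  sw <- .fg_sandwich(A, sc$U, Alist)
  se <- sqrt(diag(sw$vcov))
  beta <- stats::setNames(beta, c("(Intercept)", "A"))
  se <- stats::setNames(se, names(beta))
  .gee_result(beta, sw, se, J, conf_level, "independence", 0, it,
              estimator = "Augmented GEE")
}
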