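#' Fit a LASSO solution path by coordinate descent
#'
#' Minimizes \eqn{(2n)^{-1}\|y - Xb\|_2^2 + \lambda \|b\|_1} over a decreasing
#' grid of penalties with warm starts, using cyclic coordinate descent on the
#' Gram ("covariance") form, which is efficient when the same design is
#' revisited across many penalties. Columns are standardized internally by
#' default and coefficients are returned on the original scale, with a
#' per-penalty intercept.
#'
#' @param X Numeric design matrix (individuals x SNPs).
#' @param y Numeric response (e.g. residualized standardized SOS).
#' @param lambda Optional decreasing positive penalty grid; if `NULL`, a
#'   log-spaced grid of `n_lambda` values from `lambda_max` (the smallest
#'   penalty with an all-zero solution) down to
#'   `lambda_min_ratio * lambda_max`.
#' @param n_lambda,lambda_min_ratio Grid size and lower endpoint ratio.
#' @param standardize Standardize columns internally (default `TRUE`).
#' @param tol Convergence tolerance: largest absolute coefficient change (on
#'   the standardized scale) in a full sweep.
#' @param max_iter Maximum sweeps per penalty value.
#' @return An object of class `lasso_path`: list with `beta` (p x L matrix,
#'   original scale), `beta_std` (standardized scale), `intercept` (length L),
#'   `lambda`, `df` (nonzero counts), `iters`, and the column `center`/`scale`
#'   used.
#' @export
fit_lasso_path <- function(X, y, lambda = NULL, n_lambda = 50,
                           lambda_min_ratio = 0.001, standardize = TRUE,
                           tol = 1e-7, max_iter = 10000) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) .stopf("length(y) != nrow(X)")
  ybar <- mean(y)
  yc <- y - ybar
  if (standardize) {
    ctr <- colMeans(X)
    scl <- sqrt(colSums(X^2) / n - ctr^2)
    zero <- scl <= 1e-12
    scl[zero] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    Xs[, zero] <- 0
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
    Xs <- X
  }
  G <- crossprod(Xs) / n
  cvec <- as.numeric(crossprod(Xs, yc)) / n
  if (is.null(lambda)) {
    lmax <- max(abs(cvec))
    if (lmax <= 0) lmax <- 1e-3
    lambda <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                      length.out = n_lambda))
  } else {
    if (any(diff(lambda) >= 0) || any(lambda <= 0))
      .stopf("`lambda` must be strictly decreasing and positive")
  }
  fit <- lasso_cd_gram(G, cvec, lambda, tol, as.integer(max_iter))
  if (!all(fit$converged)) {
    bad <- which(!fit$converged)
    .stopf("coordinate descent failed to converge at %d lambda value(s) (first: lambda = %g after %d sweeps)",
           length(bad), lambda[bad[1]], max_iter)
  }
  beta_std <- fit$beta
  beta <- beta_std / scl
  intercept <- ybar - as.numeric(crossprod(beta, ctr))
  structure(list(beta = beta, beta_std = beta_std, intercept = intercept,
                 lambda = lambda, df = colSums(beta_std != 0),
                 iters = fit$iters, center = ctr, scale = scl,
                 y_center = ybar),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("LASSO path: %d predictors, %d lambda values (%.3g .. %.3g)\n",
              nrow(x$beta), length(x$lambda), max(x$lambda), min(x$lambda)))
  cat(sprintf("  nonzero coefficients: %d .. %d\n", min(x$df), max(x$df)))
  invisible(x)
}

## Karush-Kuhn-Tucker residual of a LASSO solution on the standardized scale:
## max over active j of | g_j - lambda * sign(b_j) | and over inactive j of
## max(0, |g_j| - lambda), where g = X'(y - Xb)/n. Zero at the exact optimum.
lasso_kkt_residual <- function(Xs, yc, beta_std, lambda) {
  n <- nrow(Xs)
  g <- as.numeric(crossprod(Xs, yc - Xs %*% beta_std)) / n
  act <- beta_std != 0
  v_act <- if (any(act)) max(abs(g[act] - lambda * sign(beta_std[act]))) else 0
  v_inact <- if (any(!act)) max(0, max(abs(g[!act])) - lambda) else 0
  max(v_act, v_inact)
}

## LASSO objective (2n)^-1 ||y - Xb||^2 + lambda ||b||_1
lasso_objective <- function(Xs, yc, beta_std, lambda) {
  n <- nrow(Xs)
  sum((yc - Xs %*% beta_std)^2) / (2 * n) + lambda * sum(abs(beta_std))
}
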