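new_prs_model <- function(snp_ids, effect_alleles, weights, intercept = 0,
                          p_threshold = NA_real_, lambda = NA_real_,
                          method = "lasso", standardization = NULL,
                          provenance = list(), selection_grid = NULL) {
  structure(list(
    snp_ids = snp_ids, effect_alleles = effect_alleles,
    weights = as.numeric(weights), intercept = intercept,
    p_threshold = p_threshold, lambda = lambda, method = method,
    standardization = standardization, provenance = provenance,
    selection_grid = selection_grid
  ), class = "prs_model")
}

#' Train a sparse polygenic score with held-out model selection
#'
#' The core estimator: for each p-value threshold in `p_thresholds`, the SNPs
#' whose training-set GWAS p-value passes the threshold enter a LASSO fitted
#' over a decreasing penalty path on the training set (phenotype residualized
#' against the covariates); every (threshold, lambda) pair is then scored on
#' the disjoint model-selection set and the candidate with the lowest root
#' mean square error is selected, so exactly one final score goes forward.
#' The returned model carries its sparse per-allele weights, the winning
#' threshold and penalty, and standardization constants computed on the
#' reference rows so that predictions ("gSOS") have mean 0 and SD 1 there.
#'
#' @param panel A `genotype_panel`.
#' @param phenotype Numeric phenotype (standardized SOS), one per panel row.
#' @param split A [split_cohort()] assignment (training and selection sets are
#'   used; the test set is never touched during fitting).
#' @param covariates Optional covariate matrix (e.g. age and a sex indicator);
#'   the phenotype is residualized against them, fitted on the training rows.
#' @param gwas Optional precomputed training-set [run_gwas()] table; computed
#'   internally if `NULL`.
#' @param p_thresholds Decreasing-inclusiveness grid of GWAS p-value cutoffs.
#' @param n_lambda,lambda_min_ratio Penalty-path grid per threshold.
#' @param tol,max_iter Coordinate-descent convergence controls.
#' @param reference Rows used to standardize the score: `"training"`
#'   (default), `"selection"`, or an integer index vector.
#' @return An object of class `prs_model`. `selection_grid` holds the RMSE of
#'   every candidate; `provenance` records sizes and settings.
#' @seealso [predict.prs_model()], [traditional_prs()], [variance_explained()]
#' @export
prs_fit <- function(panel, phenotype, split, covariates = NULL, gwas = NULL,
                    p_thresholds = c(5e-8, 5e-6, 5e-4, 5e-3, 5e-2, 1),
                    n_lambda = 50, lambda_min_ratio = 0.001,
                    tol = 1e-7, max_iter = 10000, reference = "training") {
  stopifnot(inherits(panel, "genotype_panel"), inherits(split, "split_assignment"))
  tr <- split$training
  sel <- split$selection
  if (!length(tr) || !length(sel)) .stopf("empty training or selection set")

  ## residualize phenotype against covariates, coefficients fitted on training
  resid_fun <- .covariate_residualizer(covariates, phenotype, tr)
  y_tr <- resid_fun(tr)
  y_sel <- resid_fun(sel)

  if (is.null(gwas)) gwas <- run_gwas(panel, phenotype, covariates, subset = tr)

  ## standardized training design and Gram matrix on the union of all
  ## thresholded SNP sets, computed once and sub-indexed per threshold
  p_thresholds <- sort(p_thresholds, decreasing = TRUE)
  union_idx <- which(gwas$p <= max(p_thresholds) & !gwas$monomorphic)
  if (!length(union_idx)) .stopf("no SNP passes the loosest p-value threshold")
  Xtr <- panel$dosages[tr, union_idx, drop = FALSE]
  ctr <- colMeans(Xtr)
  scl <- sqrt(colSums(Xtr^2) / length(tr) - ctr^2)
  ok <- scl > 1e-12
  Xs <- sweep(sweep(Xtr, 2, ctr), 2, pmax(scl, 1e-12), "/")
  Xs[, !ok] <- 0
  n_tr <- length(tr)
  ytr_c <- y_tr - mean(y_tr)
  G <- crossprod(Xs) / n_tr
  cvec <- as.numeric(crossprod(Xs, ytr_c)) / n_tr
  Xsel <- panel$dosages[sel, union_idx, drop = FALSE]

  grid <- list()
  best <- NULL
  for (thr in p_thresholds) {
    keep <- which(gwas$p[union_idx] <= thr & ok)
    if (!length(keep)) next
    lmax <- max(abs(cvec[keep]))
    if (lmax <= 0) next
    lam <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                   length.out = n_lambda))
    fit <- lasso_cd_gram(G[keep, keep, drop = FALSE], cvec[keep], lam,
                         tol, as.integer(max_iter))
    if (!all(fit$converged))
      .stopf("coordinate descent failed to converge (threshold %g)", thr)
    beta_std <- fit$beta                       # standardized scale
    beta <- beta_std / scl[keep]               # per-dosage-unit scale
    a0 <- mean(y_tr) - as.numeric(crossprod(beta, ctr[keep]))
    pred <- Xsel[, keep, drop = FALSE] %*% beta +
      rep(a0, each = length(sel))
    rmse <- sqrt(colMeans((y_sel - pred)^2))
    df <- colSums(beta_std != 0)
    grid[[length(grid) + 1L]] <- data.frame(
      p_threshold = thr, lambda = lam, df = df, rmse = rmse)
    o <- order(rmse, df, -lam)[1]
    cand <- list(p_threshold = thr, lambda = lam[o], df = df[o],
                 rmse = rmse[o], idx = union_idx[keep], beta = beta[, o],
                 intercept = a0[o])
    if (is.null(best) ||
        cand$rmse < best$rmse ||
        (cand$rmse == best$rmse && cand$df < best$df) ||
        (cand$rmse == best$rmse && cand$df == best$df &&
         cand$lambda > best$lambda)) best <- cand
  }
  if (is.null(best)) .stopf("no usable candidate model")
  nz <- best$beta != 0
  if (!any(nz)) .stopf("selected model has no nonzero weights; widen the lambda grid")

  model <- new_prs_model(
    snp_ids = panel$snp_ids[best$idx[nz]],
    effect_alleles = panel$effect_alleles[best$idx[nz]],
    weights = best$beta[nz],
    intercept = best$intercept,
    p_threshold = best$p_threshold, lambda = best$lambda, method = "lasso",
    provenance = list(n_training = n_tr, n_selection = length(sel),
                      n_snps_considered = ncol(panel$dosages),
                      p_thresholds = p_thresholds, n_lambda = n_lambda,
                      lambda_min_ratio = lambda_min_ratio, tol = tol),
    selection_grid = do.call(rbind, grid)
  )
  ref_idx <- if (is.character(reference)) split[[match.arg(reference, c("training", "selection"))]] else reference
  prs_standardize(model, panel, ref_idx)
}

## closure residualizing the phenotype against covariates with coefficients
## estimated on the training rows only
.covariate_residualizer <- function(covariates, phenotype, training_idx) {
  if (is.null(covariates)) return(function(idx) phenotype[idx])
  cv <- as.matrix(covariates)
  Ct <- cbind(1, cv[training_idx, , drop = FALSE])
  qrC <- qr(Ct)
  if (qrC$rank < ncol(Ct)) .stopf("covariate matrix is rank-deficient")
  coefs <- qr.coef(qrC, phenotype[training_idx])
  coefs[is.na(coefs)] <- 0
  function(idx) phenotype[idx] - as.numeric(cbind(1, cv[idx, , drop = FALSE]) %*% coefs)
}

#' Select the best candidate score on a held-out set
#'
#' Given candidate weight vectors (e.g. one per p-value threshold and penalty),
#' returns the candidate with the lowest prediction RMSE on the held-out
#' design/response. Exact ties break toward the sparser candidate, then toward
#' the larger penalty.
#'
#' @param candidates List of candidates; each a list with `snp_idx` (columns of
#'   `X` the weights refer to), `weights`, `intercept`, and optionally
#'   `p_threshold`, `lambda`.
#' @param X Held-out dosage matrix (all panel columns).
#' @param y Held-out response.
#' @return The winning candidate, with its `rmse` added.
#' @export
select_model <- function(candidates, X, y) {
  if (!length(candidates)) .stopf("no candidates supplied")
  stats <- lapply(candidates, function(cand) {
    pred <- as.numeric(X[, cand$snp_idx, drop = FALSE] %*% cand$weights) +
      (cand$intercept %||% 0)
    data.frame(rmse = sqrt(mean((y - pred)^2)),
               df = sum(cand$weights != 0),
               lambda = cand$lambda %||% NA_real_)
  })
  stats <- do.call(rbind, stats)
  lam <- ifelse(is.na(stats$lambda), -Inf, stats$lambda)
  o <- order(stats$rmse, stats$df, -lam)[1]
  winner <- candidates[[o]]
  winner$rmse <- stats$rmse[o]
  winner
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Traditional clump-and-threshold polygenic score
#'
#' Builds a score directly from GWAS effect sizes: SNPs are LD-clumped
#' ([ld_clump()]) at `r2_max`, restricted to `p <= p_threshold`, and the
#' per-allele weights are the (marginal) GWAS betas of the index SNPs, with no
#' joint re-fitting.
#'
#' @param gwas A `gwas_table`.
#' @param panel The matching `genotype_panel`.
#' @param p_threshold GWAS p-value cutoff.
#' @param r2_max Clumping cutoff (default 0.05).
#' @param subset Optional rows for the clumping correlations (training set).
#' @return A `prs_model` with `method = "clump_threshold"`. A model with zero
#'   SNPs is returned (with a warning) when nothing passes the threshold.
#' @export
traditional_prs <- function(gwas, panel, p_threshold, r2_max = 0.05,
                            subset = NULL) {
  idx <- ld_clump(gwas, panel, r2_max = r2_max, p_max = p_threshold,
                  subset = subset)
  if (!length(idx))
    warning("no SNP passes the p-value threshold; returning an empty score",
            call. = FALSE)
  new_prs_model(
    snp_ids = panel$snp_ids[idx],
    effect_alleles = panel$effect_alleles[idx],
    weights = gwas$beta[idx], intercept = 0,
    p_threshold = p_threshold, lambda = NA_real_,
    method = "clump_threshold",
    provenance = list(r2_max = r2_max, n = if (length(idx)) gwas$n[idx[1]] else NA)
  )
}

## raw (unstandardized) score of a model on a panel, flipping dosages where the
## panel's effect allele disagrees with the model's
.prs_raw_score <- function(model, panel, rows = NULL) {
  pos <- match(model$snp_ids, panel$snp_ids)
  if (anyNA(pos))
    .stopf("panel is missing model SNP(s): %s",
           paste(head(model$snp_ids[is.na(pos)], 5), collapse = ", "))
  X <- panel$dosages[, pos, drop = FALSE]
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  flip <- panel$effect_alleles[pos] != model$effect_alleles
  if (any(flip)) {
    warning(sprintf("%d SNP(s) with mismatched effect allele: dosages flipped (2 - d)",
                    sum(flip)), call. = FALSE)
    X[, flip] <- 2 - X[, flip]
  }
  as.numeric(X %*% model$weights) + model$intercept
}

#' Attach standardization constants to a polygenic score
#'
#' Computes the raw score on the reference rows of `panel` and stores its mean
#' and standard deviation in the model, so that subsequent predictions are
#' standardized scores with mean 0 and SD 1 on the reference set.
#'
#' @param model A `prs_model`.
#' @param panel A `genotype_panel` containing all model SNPs.
#' @param reference_idx Integer rows defining the standardization population.
#' @return The model with `$standardization` set.
#' @export
prs_standardize <- function(model, panel, reference_idx) {
  if (!length(model$weights)) .stopf("cannot standardize an empty score")
  raw <- .prs_raw_score(model, panel, reference_idx)
  s <- sd(raw)
  if (!is.finite(s) || s <= 0)
    .stopf("reference score has zero standard deviation; cannot standardize")
  model$standardization <- list(mean = mean(raw), sd = s,
                                n_reference = length(reference_idx))
  model
}

#' Predict the standardized genetic score (gSOS) for a panel
#'
#' @param object A `prs_model`.
#' @param panel A `genotype_panel` with all model SNPs (a SNP typed on the
#'   opposite allele is flipped `2 - dosage` with a warning).
#' @param type `"gsos"` (standardized; requires [prs_standardize()] constants,
#'   as set by [prs_fit()]) or `"raw"`.
#' @param rows Optional row subset.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.prs_model <- function(object, panel, type = c("gsos", "raw"),
                              rows = NULL, ...) {
  type <- match.arg(type)
  raw <- .prs_raw_score(object, panel, rows)
  if (type == "raw") return(raw)
  st <- object$standardization
  if (is.null(st))
    .stopf("model has no standardization constants; call prs_standardize() first")
  (raw - st$mean) / st$sd
}

#' @export
coef.prs_model <- function(object, ...) {
  setNames(object$weights, object$snp_ids)
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("Polygenic score (%s): %d SNPs with nonzero weight\n",
              x$method, length(x$weights)))
  if (!is.na(x$p_threshold))
    cat(sprintf("  p-value threshold %g", x$p_threshold))
  if (!is.na(x$lambda)) cat(sprintf(", lambda %.4g", x$lambda))
  cat("\n")
  if (!is.null(x$standardization))
    cat(sprintf("  standardized on %d reference individuals (raw mean %.4g, sd %.4g)\n",
                x$standardization$n_reference, x$standardization$mean,
                x$standardization$sd))
  invisible(x)
}

#' @export
summary.prs_model <- function(object, ...) {
  out <- list(model = object, grid = object$selection_grid)
  class(out) <- "summary.prs_model"
  out
}

#' @export
print.summary.prs_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$grid)) {
    agg <- do.call(rbind, lapply(split(x$grid, x$grid$p_threshold), function(d) {
      o <- which.min(d$rmse)
      data.frame(p_threshold = d$p_threshold[1], best_lambda = d$lambda[o],
                 nonzero = d$df[o], rmse = d$rmse[o])
    }))
    agg <- agg[order(-agg$p_threshold), ]
    rownames(agg) <- NULL
    cat("Best candidate per p-value threshold (held-out RMSE):\n")
    print(agg, digits = 4)
  }
  invisible(x)
}

#' Plot the model-selection surface of a fitted polygenic score
#'
#' Held-out RMSE against `log10(lambda)`, one curve per p-value threshold,
#' with the selected candidate marked.
#'
#' @param x A `prs_model` fitted by [prs_fit()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.prs_model <- function(x, ...) {
  g <- x$selection_grid
  if (is.null(g)) .stopf("model has no selection grid to plot")
  thrs <- sort(unique(g$p_threshold), decreasing = TRUE)
  graphics::plot(NULL, xlim = range(log10(g$lambda)), ylim = range(g$rmse),
                 xlab = expression(log[10](lambda)), ylab = "held-out RMSE",
                 main = "Model selection surface", ...)
  for (i in seq_along(thrs)) {
    d <- g[g$p_threshold == thrs[i], ]
    graphics::lines(log10(d$lambda), d$rmse, col = i)
  }
  graphics::points(log10(x$lambda), min(g$rmse), pch = 19)
  graphics::legend("topright", legend = sprintf("p <= %g", thrs),
                   col = seq_along(thrs), lty = 1, cex = 0.8)
  invisible(x)
}

#' Variance explained with a bootstrap confidence interval
#'
#' Squared Pearson correlation between predictions and outcome, with a
#' nonparametric percentile bootstrap over individuals.
#'
#' @param predictions,outcome Equal-length numeric vectors (`n >= 10`).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `r2` and `ci` (length-2 vector).
#' @export
variance_explained <- function(predictions, outcome, n_boot = 1000,
                               seed = NULL, conf = 0.95) {
  n <- length(outcome)
  if (length(predictions) != n) .stopf("length mismatch")
  if (n < 10) .stopf("need at least 10 observations")
  if (sd(predictions) == 0 || sd(outcome) == 0)
    .stopf("zero-variance input")
  if (!is.null(seed)) set.seed(seed)
  r2 <- cor(predictions, outcome)^2
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(predictions[idx], outcome[idx])^2)
  }, numeric(1))
  a <- (1 - conf) / 2
  list(r2 = r2, ci = unname(quantile(reps, c(a, 1 - a), na.rm = TRUE)))
}

#' Incremental variance explained by nested covariate sets
#'
#' Least-squares \eqn{r^2} of the outcome on a base covariate set and on the
#' base set plus added covariates; by nesting, the full model never explains
#' less.
#'
#' @param cohort Cohort `data.frame`.
#' @param outcome Column name in `cohort`, or a numeric vector.
#' @param base_covariates,added_covariates Character vectors of column names
#'   (`sex` and logical columns are converted to indicators).
#' @return List with `r2_base` and `r2_full`.
#' @export
incremental_r2 <- function(cohort, outcome, base_covariates,
                           added_covariates) {
  y <- if (is.character(outcome) && length(outcome) == 1L) {
    cohort[[outcome]] %||% .stopf("no column `%s`", outcome)
  } else as.numeric(outcome)
  as_num <- function(cols) {
    miss <- setdiff(cols, names(cohort))
    if (length(miss)) .stopf("covariate(s) not in cohort: %s",
                             paste(miss, collapse = ", "))
    m <- vapply(cols, function(cn) {
      v <- cohort[[cn]]
      if (is.character(v) || is.factor(v)) as.numeric(as.character(v) == "female")
      else as.numeric(v)
    }, numeric(nrow(cohort)))
    matrix(m, nrow = nrow(cohort), dimnames = list(NULL, cols))
  }
  fit_r2 <- function(X) {
    M <- cbind(1, X)
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) .stopf("collinear covariates")
    res <- qr.resid(qrM, y)
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  Xb <- as_num(base_covariates)
  Xf <- cbind(Xb, as_num(added_covariates))
  list(r2_base = fit_r2(Xb), r2_full = fit_r2(Xf))
}
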