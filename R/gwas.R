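#' Randomly split a cohort into training / model-selection / test sets
#'
#' Partitions `1:n` by a uniform random permutation cut at the cumulative
#' fractions, so realized sizes match the requested fractions within rounding.
#' The default fractions are the 80% / 1.25% / 18.75% design used to train,
#' select and test a polygenic score on disjoint data.
#'
#' @param n Number of individuals.
#' @param fractions Positive length-3 vector summing to 1:
#'   (training, selection, test).
#' @param seed Optional integer seed; the assignment is deterministic given it.
#' @return An object of class `split_assignment`: list with integer index
#'   vectors `training`, `selection`, `test`.
#' @export
split_cohort <- function(n, fractions = c(0.80, 0.0125, 0.1875), seed = NULL) {
  if (length(fractions) != 3L || any(fractions <= 0))
    .stopf("`fractions` must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9) .stopf("`fractions` must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  cuts <- round(cumsum(fractions) * n)
  cuts[3] <- n
  out <- list(training = sort(perm[seq_len(cuts[1])]),
              selection = sort(perm[seq.int(cuts[1] + 1L, cuts[2])]),
              test = sort(perm[seq.int(cuts[2] + 1L, n)]))
  class(out) <- "split_assignment"
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("Split: training %d / selection %d / test %d\n",
              length(x$training), length(x$selection), length(x$test)))
  invisible(x)
}

#' Per-SNP association scan (GWAS) by fixed-effect least squares
#'
#' Tests the additive allelic effect of each SNP on the phenotype, one SNP at
#' a time, in a linear model with the supplied covariates (plus an intercept).
#' Implemented by projecting phenotype and dosages onto the orthogonal
#' complement of the covariate space, so the per-SNP slope, standard error and
#' two-sided t-test match the full per-SNP regression exactly while the scan
#' stays fully vectorized. Monomorphic SNPs are flagged and reported with
#' `beta = 0`, `p = 1`.
#'
#' @param panel A `genotype_panel`.
#' @param phenotype Numeric vector, one value per panel row.
#' @param covariates Optional numeric matrix/data.frame of covariates (e.g.
#'   age, sex indicator, principal components from [genotype_pcs()]).
#' @param subset Optional integer indices of rows to use (e.g. the training
#'   set of a [split_cohort()] assignment).
#' @return A `data.frame` of class `gwas_table` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `beta`, `se`, `p`, `n`, `monomorphic`.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL, subset = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(phenotype) != nrow(panel$dosages))
    .stopf("phenotype length (%d) != panel rows (%d)",
           length(phenotype), nrow(panel$dosages))
  if (is.null(subset)) subset <- seq_len(nrow(panel$dosages))
  y <- phenotype[subset]
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    C <- cbind(C, cv[subset, , drop = FALSE])
  }
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) .stopf("covariate matrix is rank-deficient")
  yr <- qr.resid(qrC, y)
  Xr <- qr.resid(qrC, panel$dosages[subset, , drop = FALSE])
  sxx <- colSums(Xr^2)
  sxy <- as.numeric(crossprod(Xr, yr))
  syy <- sum(yr^2)
  mono <- sxx < 1e-10
  beta <- ifelse(mono, 0, sxy / sxx)
  df <- n - qrC$rank - 1L
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / df / sxx))
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]
  p[mono] <- 1
  out <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                    pos = panel$positions,
                    effect_allele = panel$effect_alleles,
                    beta = beta, se = se, p = p, n = n,
                    monomorphic = mono, stringsAsFactors = FALSE)
  class(out) <- c("gwas_table", "data.frame")
  out
}

#' Leading principal components of a genotype panel
#'
#' Principal components of the column-standardized dosage matrix, computed via
#' the SNP-by-SNP Gram matrix (suitable for panels with many more individuals
#' than SNPs). Useful as GWAS covariates when population structure is a
#' concern.
#'
#' @param panel A `genotype_panel`.
#' @param k Number of components.
#' @param subset Optional row indices.
#' @return Numeric matrix (`length(subset)` x `k`) of component scores.
#' @export
genotype_pcs <- function(panel, k = 10, subset = NULL) {
  X <- panel$dosages
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  G <- crossprod(Xs) / nrow(Xs)
  ev <- eigen(G, symmetric = TRUE)
  k <- min(k, sum(ev$values > 1e-12))
  scores <- Xs %*% ev$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Greedy LD clumping of GWAS results
#'
#' Repeatedly takes the most significant unassigned SNP with `p <= p_max` as an
#' index SNP and removes all remaining SNPs whose squared dosage correlation
#' with it exceeds `r2_max`, yielding a set of approximately
#' linkage-independent index SNPs. Ties on p-value break toward the smaller
#' column index; correlations are computed on `subset` (e.g. the training set).
#'
#' @param gwas A `gwas_table` from [run_gwas()].
#' @param panel The matching `genotype_panel`.
#' @param r2_max Squared-correlation cutoff in (0, 1) (default 0.05).
#' @param p_max Largest p-value eligible to index a clump.
#' @param subset Optional row indices for the correlation computation.
#' @return Integer vector of panel column indices of the index SNPs, in
#'   selection order (most significant first). May be empty.
#' @export
ld_clump <- function(gwas, panel, r2_max = 0.05, p_max = 1, subset = NULL) {
  .assert_scalar_prob(r2_max, "r2_max")
  cand <- which(gwas$p <= p_max & !gwas$monomorphic)
  if (!length(cand)) return(integer(0))
  ord <- cand[order(gwas$p[cand], cand)]
  X <- panel$dosages[, ord, drop = FALSE]
  if (!is.null(subset)) X <- X[subset, , drop = FALSE]
  R2 <- suppressWarnings(cor(X))^2
  R2[is.na(R2)] <- 0
  alive <- rep(TRUE, length(ord))
  picked <- integer(0)
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    picked <- c(picked, ord[i])
    alive <- alive & R2[i, ] <= r2_max
    alive[i] <- FALSE
  }
  picked
}
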