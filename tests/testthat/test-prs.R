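# Shared small training setup for the score-fitting tests.
prs_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    panel <- simulate_genotypes(4000, 300, block_size = 10, block_rho = 0.7,
                                seed = 201)
    ph <- simulate_phenotypes(panel, n_causal = 40, h2_sos = 0.3, seed = 202)
    split <- split_cohort(4000, c(0.7, 0.1, 0.2), seed = 203)
    gwas <- run_gwas(panel, ph$sos_std, subset = split$training)
    cache <<- list(panel = panel, ph = ph, split = split, gwas = gwas)
    cache
  }
})

test_that("fitting selects one model and standardizes it on the reference set", {
  fx <- prs_fixture()
  fit <- prs_fit(fx$panel, fx$ph$sos_std, fx$split, gwas = fx$gwas,
                 p_thresholds = c(5e-4, 5e-2, 1), n_lambda = 25)
  expect_s3_class(fit, "prs_model")
  expect_gt(length(fit$weights), 0)
  expect_true(fit$p_threshold %in% c(5e-4, 5e-2, 1))
  g_ref <- predict(fit, fx$panel, rows = fx$split$training)
  expect_lt(abs(mean(g_ref)), 1e-10)
  expect_equal(sd(g_ref), 1, tolerance = 1e-10)
  # the selected candidate has the smallest held-out RMSE in its own grid
  expect_equal(min(fit$selection_grid$rmse),
               fit$selection_grid$rmse[
                 fit$selection_grid$p_threshold == fit$p_threshold &
                   fit$selection_grid$lambda == fit$lambda])
  # methods run
  expect_output(print(fit), "Polygenic score")
  expect_output(print(summary(fit)), "p-value threshold")
  expect_named(coef(fit))
})

test_that("LASSO weights are attenuated relative to GWAS betas for activated SNPs", {
  fx <- prs_fixture()
  fit <- prs_fit(fx$panel, fx$ph$sos_std, fx$split, gwas = fx$gwas,
                 p_thresholds = c(5e-4, 5e-2, 1), n_lambda = 25)
  pos <- match(fit$snp_ids, fx$panel$snp_ids)
  sds <- apply(fx$panel$dosages[fx$split$training, pos, drop = FALSE], 2, sd)
  w_std <- abs(fit$weights) * sds         # standardized-design scale
  b_std <- abs(fx$gwas$beta[pos]) * sds
  # under LD a jointly fitted SNP can occasionally absorb its neighbours"
  # signal, so attenuation holds for the large majority and in aggregate,
  # not SNP-by-SNP
  expect_gt(mean(w_std <= b_std + 1e-8), 0.8)
  expect_lt(median(w_std / b_std), 1)
  expect_lt(sum(w_std), sum(b_std))
})

test_that("model selection prefers lower RMSE, then sparsity, then larger penalty", {
  set.seed(211)
  X <- matrix(rnorm(500 * 6), 500, 6)
  y <- as.numeric(X[, 1] + rnorm(500, sd = 0.2))
  truth <- list(snp_idx = 1L, weights = 1, intercept = 0, lambda = 0.5)
  noise <- list(snp_idx = 2L, weights = 1, intercept = 0, lambda = 0.5)
  got <- select_model(list(noise, truth), X, y)
  expect_identical(got$snp_idx, 1L)
  # exact tie on rmse (duplicated predictor): the sparser candidate wins
  X[, 4] <- X[, 1]
  a <- list(snp_idx = c(1L, 4L), weights = c(0.5, 0.5), intercept = 0,
            lambda = 0.1)
  b <- list(snp_idx = 1L, weights = 1, intercept = 0, lambda = 0.1)
  expect_identical(select_model(list(a, b), X, y)$snp_idx, 1L)
  # tie on rmse and sparsity: the larger penalty wins
  c1 <- list(snp_idx = 1L, weights = 1, intercept = 0, lambda = 0.1)
  c2 <- list(snp_idx = 1L, weights = 1, intercept = 0, lambda = 0.9)
  expect_equal(select_model(list(c1, c2), X, y)$lambda, 0.9)
  expect_identical(select_model(list(truth), X, y)$snp_idx, 1L)
  expect_error(select_model(list(), X, y), "candidates")
})

test_that("traditional score is the clumped GWAS-beta dosage sum", {
  fx <- prs_fixture()
  tm <- traditional_prs(fx$gwas, fx$panel, p_threshold = 5e-3,
                        subset = fx$split$training)
  idx <- match(tm$snp_ids, fx$panel$snp_ids)
  expect_true(all(fx$gwas$p[idx] <= 5e-3))
  expect_equal(tm$weights, fx$gwas$beta[idx])
  # oracle recomputation by explicit loop
  sc <- predict(tm, fx$panel, type = "raw", rows = 1:50)
  manual <- sapply(1:50, function(i)
    sum(fx$panel$dosages[i, idx] * fx$gwas$beta[idx]))
  expect_equal(sc, manual)
  # tightening the threshold never increases the SNP count
  tm2 <- traditional_prs(fx$gwas, fx$panel, p_threshold = 5e-5,
                         subset = fx$split$training)
  expect_lte(length(tm2$weights), length(tm$weights))
  expect_warning(traditional_prs(fx$gwas, fx$panel, p_threshold = 0),
                 "empty")
})

test_that("single clumped SNP gives score = beta x dosage", {
  p <- simulate_genotypes(100, 1, seed = 212)
  g <- data.frame(snp_id = p$snp_ids, beta = 0.3, p = 1e-10,
                  monomorphic = FALSE)
  m <- traditional_prs(g, p, p_threshold = 1e-8)
  expect_equal(predict(m, p, type = "raw"), 0.3 * p$dosages[, 1])
})

test_that("scoring is invariant to SNP column order and flips mismatched alleles", {
  fx <- prs_fixture()
  fit <- prs_fit(fx$panel, fx$ph$sos_std, fx$split, gwas = fx$gwas,
                 p_thresholds = c(5e-2, 1), n_lambda = 15)
  g1 <- predict(fit, fx$panel)
  set.seed(213)
  perm <- sample(ncol(fx$panel$dosages))
  panel2 <- fx$panel
  panel2$dosages <- panel2$dosages[, perm]
  panel2$snp_ids <- panel2$snp_ids[perm]
  panel2$effect_alleles <- panel2$effect_alleles[perm]
  expect_equal(predict(fit, panel2), g1)
  # flipped effect allele: dosage 2 - d recovers the same score
  panel3 <- fx$panel
  j <- match(fit$snp_ids[1], panel3$snp_ids)
  panel3$effect_alleles[j] <- setdiff(c("A", "C", "G", "T"),
                                      panel3$effect_alleles[j])[1]
  panel3$dosages[, j] <- 2 - panel3$dosages[, j]
  expect_warning(g3 <- predict(fit, panel3), "flipped")
  expect_equal(g3, g1)
  # missing SNP errors with its id
  panel4 <- fx$panel
  panel4$snp_ids[match(fit$snp_ids[1], panel4$snp_ids)] <- "zzz"
  expect_error(predict(fit, panel4), fit$snp_ids[1])
})

test_that("standardization contracts: zero-weight and unstandardized models error", {
  fx <- prs_fixture()
  m0 <- gsosScreen:::new_prs_model(snp_ids = fx$panel$snp_ids[1],
                                   effect_alleles = fx$panel$effect_alleles[1],
                                   weights = 0)
  expect_error(prs_standardize(m0, fx$panel, 1:100), "zero standard deviation")
  m1 <- gsosScreen:::new_prs_model(snp_ids = fx$panel$snp_ids[1],
                                   effect_alleles = fx$panel$effect_alleles[1],
                                   weights = 0.5)
  expect_error(predict(m1, fx$panel), "standardization")
})

test_that("variance explained: exact, null, and invariance cases", {
  set.seed(221)
  x <- rnorm(5000)
  v <- variance_explained(x, x, n_boot = 50, seed = 1)
  expect_equal(v$r2, 1)
  y <- rnorm(5000)
  v0 <- variance_explained(x, y, n_boot = 200, seed = 2)
  expect_lt(v0$r2, 0.005)
  expect_lt(v0$ci[1], v0$r2)
  # linear transforms leave r2 unchanged
  z <- rnorm(5000); w <- z + rnorm(5000)
  expect_equal(variance_explained(3 * z - 7, w, n_boot = 10, seed = 3)$r2,
               variance_explained(z, w, n_boot = 10, seed = 3)$r2)
  expect_error(variance_explained(rep(1, 20), rnorm(20)), "zero-variance")
  expect_error(variance_explained(rnorm(5), rnorm(5)), "at least 10")
})

test_that("incremental r2 is monotone under nesting and exact for self-prediction", {
  ch <- simulate_risk_factors(5000, seed = 222)
  set.seed(223)
  ch$sos_std <- -0.01 * ch$age + 0.1 * (ch$sex == "female") + rnorm(5000)
  ch$noise <- rnorm(5000)
  r <- incremental_r2(ch, "sos_std", c("age", "sex", "bmi"),
                      c("smoking", "prior_fracture"))
  expect_gte(r$r2_full, r$r2_base)
  rn <- incremental_r2(ch, "sos_std", c("age", "sex"), "noise")
  expect_lt(rn$r2_full - rn$r2_base, 1e-3)
  rs <- incremental_r2(ch, "sos_std", "age", "sos_std")
  expect_equal(rs$r2_full, 1)
  ch$dup <- ch$age
  expect_error(incremental_r2(ch, "sos_std", c("age", "dup"), "bmi"),
               "collinear")
})
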