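#' Simulate LD-structured biallelic genotype dosages
#'
#' Generates a hard-call dosage matrix (0/1/2 copies of the effect allele) for
#' `n_individuals` individuals at `n_snps` SNPs. Linkage disequilibrium is
#' modelled with a block-autoregressive latent Gaussian: within consecutive
#' blocks of `block_size` SNPs the latent variables follow an AR(1) process with
#' correlation `block_rho`, and each of the two allele draws per individual is
#' obtained by thresholding its latent variable at the Gaussian quantile of the
#' SNP's allele frequency, so Hardy-Weinberg proportions hold marginally and
#' adjacent SNPs within a block are in positive LD.
#'
#' @param n_individuals Number of individuals (rows).
#' @param n_snps Number of SNPs (columns).
#' @param maf_range Length-2 interval within (0, 0.5] from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param block_size Number of consecutive SNPs per LD block.
#' @param block_rho AR(1) latent correlation within a block, in `[0, 1)`.
#'   `0` gives independent SNPs.
#' @param seed Optional integer seed; fixing it fixes the whole panel.
#' @return An object of class `genotype_panel`: a list with `dosages`
#'   (numeric matrix), `snp_ids`, `chrom`, `positions`, `effect_alleles`,
#'   `other_alleles` and `allele_freqs` (generating frequency of the effect
#'   allele, equal to the MAF draw).
#' @examples
#' p <- simulate_genotypes(100, 20, block_size = 5, block_rho = 0.8, seed = 1)
#' range(p$dosages)
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.5),
                               block_size = 10, block_rho = 0.8,
                               seed = NULL) {
  if (n_individuals < 1 || n_snps < 1) .stopf("need at least 1 individual and 1 SNP")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    .stopf("`maf_range` must be an interval within (0, 0.5]")
  if (!is.numeric(block_rho) || block_rho < 0 || block_rho >= 1)
    .stopf("`block_rho` must lie in [0, 1)")
  if (block_size < 1) .stopf("`block_size` must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  maf <- runif(n_snps, maf_range[1], maf_range[2])
  thr <- qnorm(maf)
  dos <- matrix(0, n_individuals, n_snps)
  rho2 <- sqrt(1 - block_rho^2)
  for (h in 1:2) { # two haplotypes per individual
    z <- numeric(n_individuals)
    for (j in seq_len(n_snps)) {
      e <- rnorm(n_individuals)
      new_block <- ((j - 1L) %% block_size) == 0L
      z <- if (new_block) e else block_rho * z + rho2 * e
      dos[, j] <- dos[, j] + (z < thr[j])
    }
  }

  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_snps, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1),
               USE.NAMES = FALSE)
  panel <- list(
    dosages = dos,
    snp_ids = sprintf("snp%05d", seq_len(n_snps)),
    chrom = rep(1L, n_snps),
    positions = seq_len(n_snps) * 5000L,
    effect_alleles = ea,
    other_alleles = oa,
    allele_freqs = maf,
    block_size = as.integer(block_size),
    block_rho = block_rho
  )
  colnames(panel$dosages) <- panel$snp_ids
  class(panel) <- "genotype_panel"
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  allele frequencies in [%.3f, %.3f]; LD blocks of %d SNPs (rho = %.2f)\n",
              min(x$allele_freqs), max(x$allele_freqs), x$block_size, x$block_rho))
  invisible(x)
}

#' Simulate the quantitative phenotypes: standardized SOS and femoral-neck BMD
#'
#' Draws a standardized heel-ultrasound speed-of-sound phenotype (`sos_std`)
#' with a target fraction `h2_sos` of its variance explained by a true
#' polygenic score over `n_causal` randomly chosen SNPs, plus a femoral-neck
#' BMD T-score correlated with SOS at `sos_bmd_corr` after removing the age and
#' sex trend in BMD. The BMD mean declines linearly with age after 50 and is
#' shifted down in women; both trends are configurable.
#'
#' @param panel A `genotype_panel`.
#' @param n_causal Number of causal SNPs (`<= n_snps`).
#' @param h2_sos Target fraction of SOS variance from genotype, in (0, 1).
#' @param sos_bmd_corr Correlation between `sos_std` and the de-trended BMD
#'   T-score, in (0, 1].
#' @param age,sex Optional per-individual vectors used for the BMD location
#'   trend; if omitted the trend terms are zero.
#' @param age_bmd_slope Change in mean T-score per year of age above 50
#'   (default -0.02).
#' @param sex_bmd_offset Additive shift in mean T-score for women (default -0.3).
#' @param bmd_t_base Mean T-score of a 50-year-old man (default -0.5).
#' @param seed Optional integer seed.
#' @return A list with `sos_std`, `fn_bmd_tscore`, and `truth`, an object of
#'   class `true_genetic_model` holding `causal_indices`, `causal_effects`
#'   (per-dosage-unit effects on the standardized scale), the realized
#'   standardized `genetic_score`, `h2_target` and the realized `h2`.
#' @export
simulate_phenotypes <- function(panel, n_causal, h2_sos = 0.25,
                                sos_bmd_corr = 0.5,
                                age = NULL, sex = NULL,
                                age_bmd_slope = -0.02, sex_bmd_offset = -0.3,
                                bmd_t_base = -0.5, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  p <- ncol(panel$dosages)
  if (n_causal < 1 || n_causal > p) .stopf("`n_causal` must be in [1, n_snps]")
  .assert_scalar_prob(h2_sos, "h2_sos")
  .assert_scalar_prob(sos_bmd_corr, "sos_bmd_corr", open_hi = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ci <- sort(sample.int(p, n_causal))
  eff <- rnorm(n_causal)
  g <- as.numeric(panel$dosages[, ci, drop = FALSE] %*% eff)
  if (sd(g) == 0) .stopf("true genetic score has zero variance; increase n or MAF")
  gs <- as.numeric(scale(g))
  sos <- sqrt(h2_sos) * gs + sqrt(1 - h2_sos) * rnorm(n)
  sos_std <- as.numeric(scale(sos))

  trend <- rep(bmd_t_base, n)
  if (!is.null(age)) trend <- trend + age_bmd_slope * pmax(age - 50, 0)
  if (!is.null(sex)) trend <- trend + sex_bmd_offset * (as.character(sex) == "female")
  bmd_resid <- sos_bmd_corr * sos_std +
    sqrt(1 - sos_bmd_corr^2) * rnorm(n)
  fn_bmd_tscore <- trend + bmd_resid

  truth <- structure(list(
    causal_indices = ci,
    ## per-dosage effect on the standardized SOS scale
    causal_effects = sqrt(h2_sos) * eff / sd(g) / sd(sos),
    genetic_score = gs,
    h2_target = h2_sos,
    h2 = cor(gs, sos_std)^2
  ), class = "true_genetic_model")

  list(sos_std = sos_std, fn_bmd_tscore = fn_bmd_tscore, truth = truth)
}

#' @export
print.true_genetic_model <- function(x, ...) {
  cat(sprintf("True genetic model: %d causal SNPs, target h2 = %.3f (realized %.3f)\n",
              length(x$causal_indices), x$h2_target, x$h2))
  invisible(x)
}

#' Default prevalences of the binary FRAX clinical risk factors
#'
#' Rates typical of a large mid-life population cohort (UK-Biobank-like) for
#' most factors; alcohol intake above two daily units and parental history of
#' hip fracture use rates typical of the Canadian Longitudinal Study on Aging,
#' since large UK cohorts often lack those fields.
#'
#' @return Named numeric vector of prevalences in `[0, 1]`.
#' @export
default_prevalences <- function() {
  c(prior_fracture = 0.102, smoking = 0.080, glucocorticoids = 0.010,
    rheumatoid_arthritis = 0.010, secondary_osteoporosis = 0.043,
    parental_hip_fracture = 0.122, alcohol = 0.177)
}

#' Simulate FRAX clinical risk factors and demographics
#'
#' Draws age (uniform on `age_range`), sex, BMI (truncated normal) and the
#' seven binary FRAX clinical risk factors as independent Bernoulli variables
#' at the supplied prevalences. Prior fracture and glucocorticoid use (or any
#' factor) may be given a logistic age tilt: the per-individual log-odds is the
#' baseline logit plus `tilt * (age - midpoint(age_range))`, so a positive tilt
#' makes the factor more common at older ages while leaving the rate at the
#' mid-age roughly at its nominal value.
#'
#' @param n Number of individuals.
#' @param age_range Length-2 interval of ages in years.
#' @param female_fraction Probability an individual is female.
#' @param prevalence Named vector of rates for (a subset of) the factors in
#'   [risk_factor_names()]; unnamed factors default to [default_prevalences()].
#' @param age_tilt Named vector of per-year log-odds slopes (default all 0).
#' @param bmi_mean,bmi_sd Normal BMI parameters (kg/m^2), truncated to `[15, 55]`.
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `id`, `age`, `sex`, `bmi` and one
#'   logical column per risk factor.
#' @export
simulate_risk_factors <- function(n, age_range = c(50, 85),
                                  female_fraction = 0.556,
                                  prevalence = NULL, age_tilt = NULL,
                                  bmi_mean = 27.5, bmi_sd = 4.5,
                                  seed = NULL) {
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    .stopf("`age_range` must be a non-empty interval")
  .assert_scalar_prob(female_fraction, "female_fraction",
                      open_lo = FALSE, open_hi = FALSE)
  rates <- default_prevalences()
  if (!is.null(prevalence)) {
    bad <- setdiff(names(prevalence), names(rates))
    if (length(bad)) .stopf("unknown risk factor(s): %s", paste(bad, collapse = ", "))
    if (any(prevalence < 0 | prevalence > 1)) .stopf("prevalences must be in [0, 1]")
    rates[names(prevalence)] <- prevalence
  }
  tilt <- setNames(numeric(length(rates)), names(rates))
  if (!is.null(age_tilt)) {
    bad <- setdiff(names(age_tilt), names(tilt))
    if (length(bad)) .stopf("unknown risk factor(s) in `age_tilt`: %s",
                            paste(bad, collapse = ", "))
    tilt[names(age_tilt)] <- age_tilt
  }
  if (!is.null(seed)) set.seed(seed)

  age <- runif(n, age_range[1], age_range[2])
  sex <- ifelse(runif(n) < female_fraction, "female", "male")
  bmi <- pmin(pmax(rnorm(n, bmi_mean, bmi_sd), 15), 55)
  out <- data.frame(id = sprintf("id%07d", seq_len(n)), age = age, sex = sex,
                    bmi = bmi, stringsAsFactors = FALSE)
  mid <- mean(age_range)
  for (f in names(rates)) {
    p <- if (rates[[f]] <= 0) {
      rep(0, n)
    } else if (rates[[f]] >= 1) {
      rep(1, n)
    } else {
      plogis(qlogis(rates[[f]]) + tilt[[f]] * (age - mid))
    }
    out[[f]] <- runif(n) < p
  }
  out
}

#' Assemble a cohort table from its simulated parts
#'
#' Joins risk factors/demographics with the simulated phenotypes (and
#' optionally a genotype panel and a gSOS column) into a single cohort table
#' keyed by `id`.
#'
#' @param risk_factors Output of [simulate_risk_factors()] (or any data frame
#'   with an `id` column and the risk-factor fields).
#' @param phenotypes Optional output of [simulate_phenotypes()].
#' @param panel Optional `genotype_panel`; only checked for a matching row count.
#' @param gsos Optional numeric vector of standardized genetic scores.
#' @return A cohort `data.frame`.
#' @export
assemble_cohort <- function(risk_factors, phenotypes = NULL, panel = NULL,
                            gsos = NULL) {
  n <- nrow(risk_factors)
  if (anyDuplicated(risk_factors$id)) .stopf("duplicate `id` in risk factors")
  if (!is.null(panel) && nrow(panel$dosages) != n)
    .stopf("genotype panel has %d rows but cohort has %d", nrow(panel$dosages), n)
  out <- risk_factors
  if (!is.null(phenotypes)) {
    if (length(phenotypes$sos_std) != n)
      .stopf("phenotypes have %d rows but cohort has %d",
             length(phenotypes$sos_std), n)
    out$fn_bmd_tscore <- phenotypes$fn_bmd_tscore
    out$sos_std <- phenotypes$sos_std
  }
  if (!is.null(gsos)) {
    if (length(gsos) != n) .stopf("`gsos` has wrong length")
    out$gsos <- gsos
  }
  out
}

#' Default risk-factor prevalences of a screening-phase validation population
#'
#' Pooled whole-cohort rates typical of the older validation cohorts in which
#' staged fracture-risk screening is evaluated (higher prior-fracture and
#' glucocorticoid rates than the mid-life training population of
#' [default_prevalences()]).
#'
#' @return Named numeric vector of prevalences.
#' @export
validation_prevalences <- function() {
  c(prior_fracture = 0.203, smoking = 0.100, glucocorticoids = 0.039,
    rheumatoid_arthritis = 0.034, secondary_osteoporosis = 0.024,
    parental_hip_fracture = 0.093, alcohol = 0.071)
}

#' Simulate a screening-ready cohort without genotypes
#'
#' Convenience generator for screening experiments: produces a cohort of
#' exactly `n_eligible` screening-eligible individuals (age at least
#' `min_age`, at least one clinical risk factor, BMD T-score present) with a
#' standardized gSOS column correlated with the de-trended BMD T-score at
#' `gsos_bmd_corr`. gSOS is standardized in the full simulated population
#' (before the eligibility filter), mirroring a score standardized in a
#' general-population training resource. Defaults emulate a pooled
#' older validation population of the kind staged screening is evaluated in
#' ([validation_prevalences()]; slight male excess among the eligible),
#' rather than the mid-life training population of [simulate_risk_factors()].
#'
#' @param n_eligible Number of eligible individuals to return.
#' @param gsos_bmd_corr Correlation between gSOS and the de-trended BMD
#'   T-score (default 0.45).
#' @param sos_bmd_corr Correlation between SOS and de-trended BMD (default 0.5).
#' @param age_range,female_fraction,prevalence,age_tilt Passed to
#'   [simulate_risk_factors()].
#' @param min_age Eligibility age floor (default 50).
#' @param seed Optional integer seed.
#' @return A cohort `data.frame` of `n_eligible` rows with `gsos`,
#'   `fn_bmd_tscore` and `sos_std` columns.
#' @export
simulate_screening_cohort <- function(n_eligible = 10000,
                                      gsos_bmd_corr = 0.45,
                                      sos_bmd_corr = 0.5,
                                      age_range = c(50, 85),
                                      female_fraction = 0.46,
                                      prevalence = validation_prevalences(),
                                      age_tilt = NULL,
                                      min_age = 50, seed = NULL) {
  .assert_scalar_prob(gsos_bmd_corr, "gsos_bmd_corr", open_hi = FALSE)
  if (!is.null(seed)) set.seed(seed)
  got <- list()
  n_got <- 0L
  while (n_got < n_eligible) {
    m <- max(2000L, ceiling((n_eligible - n_got) / 0.35))
    rf <- simulate_risk_factors(m, age_range = age_range,
                                female_fraction = female_fraction,
                                prevalence = prevalence, age_tilt = age_tilt)
    sos_std <- rnorm(m)
    trend <- -0.5 - 0.02 * pmax(rf$age - 50, 0) - 0.3 * (rf$sex == "female")
    bmd_resid <- sos_bmd_corr * sos_std + sqrt(1 - sos_bmd_corr^2) * rnorm(m)
    fn <- trend + bmd_resid
    gsos <- gsos_bmd_corr * bmd_resid + sqrt(1 - gsos_bmd_corr^2) * rnorm(m)
    ch <- rf
    ch$fn_bmd_tscore <- fn
    ch$sos_std <- sos_std
    ch$gsos <- gsos
    keep <- ch$age >= min_age &
      rowSums(as.matrix(ch[.risk_factor_names])) >= 1 &
      !is.na(ch$fn_bmd_tscore)
    got[[length(got) + 1L]] <- ch[keep, , drop = FALSE]
    n_got <- n_got + sum(keep)
  }
  out <- do.call(rbind, got)[seq_len(n_eligible), , drop = FALSE]
  out$id <- sprintf("id%07d", seq_len(n_eligible))
  rownames(out) <- NULL
  out
}
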