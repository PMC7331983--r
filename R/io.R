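.cohort_numeric_cols <- c("age", "bmi", "fn_bmd_tscore", "sos_std", "gsos",
                          "crf_frax", "bmd_frax")
.cohort_known_cols <- c("id", "age", "sex", "bmi", .risk_factor_names,
                        "fn_bmd_tscore", "sos_std", "gsos",
                        "crf_frax", "bmd_frax")

#' Write / read a cohort table as TSV
#'
#' Fixed-header tab-separated format: booleans as 0/1, missing values as empty
#' fields, `sex` as `female`/`male`. `read_cohort(write_cohort(x))` restores
#' the table (column types included).
#'
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   typed cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (f in intersect(.risk_factor_names, names(out)))
    out[[f]] <- as.integer(out[[f]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- read.delim(path, colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
  unknown <- setdiff(names(raw), .cohort_known_cols)
  if (length(unknown)) .stopf("unknown column(s) in %s: %s", path,
                              paste(unknown, collapse = ", "))
  out <- raw
  parse_num <- function(col) {
    v <- raw[[col]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) .stopf("non-numeric `%s` value '%s' at row %d",
                            col, v[bad[1]], bad[1])
    num
  }
  for (col in intersect(.cohort_numeric_cols, names(raw)))
    out[[col]] <- parse_num(col)
  if ("sex" %in% names(raw)) {
    bad <- which(!raw$sex %in% c("female", "male"))
    if (length(bad)) .stopf("malformed `sex` value '%s' at row %d",
                            raw$sex[bad[1]], bad[1])
  }
  for (f in intersect(.risk_factor_names, names(raw))) {
    v <- raw[[f]]
    bad <- which(!v %in% c("0", "1", ""))
    if (length(bad)) .stopf("malformed boolean `%s` value '%s' at row %d",
                            f, v[bad[1]], bad[1])
    out[[f]] <- ifelse(v == "", NA, v == "1")
  }
  out
}

#' Read a genotype matrix (PLINK .raw dialect or VCF)
#'
#' `format = "raw"`: whitespace-separated text with header columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `SNPID_A` column per SNP
#' whose values are dosage counts of allele `A`. `format = "vcf"`: a VCF with
#' GT genotypes (requires the vcfR package); dosages count the ALT allele
#' (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`). Missing genotypes are an error — no
#' imputation is attempted.
#'
#' @param path File path.
#' @param format `"raw"` or `"vcf"`.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, format = c("raw", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(.read_genotypes_vcf(path))
  nf <- utils::count.fields(path)
  if (length(unique(nf)) != 1L)
    .stopf("truncated or ragged line at row %d of %s",
           which(nf != nf[1])[1], path)
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(names(tab)[seq_along(fixed)], fixed))
    .stopf("not a PLINK .raw header: expected columns %s",
           paste(fixed, collapse = " "))
  snp_cols <- names(tab)[-seq_along(fixed)]
  m <- regmatches(snp_cols, regexec("^(.*)_([ACGT])$", snp_cols))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) .stopf("cannot parse SNP column name '%s'", snp_cols[bad[1]])
  ids <- vapply(m, `[`, character(1), 2)
  ea <- vapply(m, `[`, character(1), 3)
  dos <- as.matrix(tab[snp_cols])
  if (anyNA(dos)) .stopf("missing genotype dosage(s); no imputation is done")
  if (any(dos < 0 | dos > 2)) .stopf("dosages outside [0, 2]")
  storage.mode(dos) <- "double"
  colnames(dos) <- ids
  structure(list(
    dosages = dos, snp_ids = ids, chrom = rep(NA_integer_, length(ids)),
    positions = seq_along(ids), effect_alleles = ea,
    other_alleles = rep(NA_character_, length(ids)),
    allele_freqs = colMeans(dos) / 2,
    sample_ids = tab$IID
  ), class = "genotype_panel")
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    .stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) .stopf("missing GT genotype(s); no imputation is done")
  map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
           "1/1" = 2, "1|1" = 2)
  dos <- map[gt]
  if (anyNA(dos)) .stopf("unsupported GT value '%s'", gt[which(is.na(dos))[1]])
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  dosT <- t(dos) # individuals x SNPs
  ids <- unname(fix[, "ID"])
  colnames(dosT) <- ids
  structure(list(
    dosages = dosT, snp_ids = ids,
    chrom = suppressWarnings(as.integer(fix[, "CHROM"])),
    positions = as.integer(fix[, "POS"]),
    effect_alleles = unname(fix[, "ALT"]),
    other_alleles = unname(fix[, "REF"]),
    allele_freqs = colMeans(dosT) / 2,
    sample_ids = rownames(dosT)
  ), class = "genotype_panel")
}

#' Write / read a polygenic score model
#'
#' The weights are written as a PGS-Catalog-style scoring file (TSV with
#' `rsID`, `effect_allele`, `effect_weight`), and the intercept,
#' standardization constants and training provenance as a YAML sidecar at
#' `<path>.yml`.
#'
#' @param model A `prs_model`.
#' @param path Path of the scoring TSV.
#' @return `write_prs_model` returns `path` invisibly; `read_prs_model`
#'   returns the reconstructed `prs_model`.
#' @export
write_prs_model <- function(model, path) {
  write.table(
    data.frame(rsID = model$snp_ids, effect_allele = model$effect_alleles,
               effect_weight = model$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(method = model$method,
               intercept = model$intercept,
               p_threshold = model$p_threshold,
               lambda = if (is.na(model$lambda)) NULL else model$lambda,
               standardization = model$standardization,
               provenance = model$provenance)
  yaml::write_yaml(side, paste0(path, ".yml"), precision = 17L)
  invisible(path)
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rsID", "effect_allele", "effect_weight") %in% names(tab)))
    .stopf("not a scoring file: %s", path)
  side_path <- paste0(path, ".yml")
  side <- if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
  new_prs_model(
    snp_ids = tab$rsID, effect_alleles = tab$effect_allele,
    weights = tab$effect_weight,
    intercept = side$intercept %||% 0,
    p_threshold = side$p_threshold %||% NA_real_,
    lambda = side$lambda %||% NA_real_,
    method = side$method %||% "external",
    standardization = side$standardization,
    provenance = side$provenance %||% list()
  )
}

#' Default end-to-end pipeline configuration
#'
#' Nested list of every stage's parameters plus the global seed. Per-stage
#' seeds are derived deterministically from the global seed, so any stage can
#' be rerun in isolation and a rerun of the whole pipeline is reproducible.
#'
#' @param seed Global integer seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genotypes = list(n_individuals = 5000L, n_snps = 1000L,
                     maf_range = c(0.05, 0.5), block_size = 10L,
                     block_rho = 0.8),
    phenotypes = list(n_causal = 100L, h2_sos = 0.25, sos_bmd_corr = 0.5),
    risk_factors = list(age_range = c(50, 85), female_fraction = 0.556),
    split = list(fractions = c(0.80, 0.0125, 0.1875)),
    prs = list(p_thresholds = c(5e-8, 5e-6, 5e-4, 5e-3, 5e-2, 1),
               n_lambda = 50L, lambda_min_ratio = 0.001,
               clump_r2_max = 0.05),
    frax_surrogate = lapply(formals(frax_params), eval),
    screening = list(gsos_threshold_male = 0.5, gsos_threshold_female = 0,
                     gate_placement = "before_crf")
  )
}

#' Read a pipeline configuration from YAML, rejecting unknown keys
#'
#' @param path YAML file.
#' @return Configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  check <- function(user, ref, prefix = "") {
    bad <- setdiff(names(user), names(ref))
    if (length(bad)) .stopf("unknown config key(s): %s",
                            paste0(prefix, bad, collapse = ", "))
    for (k in names(user)) {
      if (is.list(ref[[k]]) && is.list(user[[k]]))
        check(user[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
  check(cfg, base)
  modifyList(base, cfg)
}

#' Run the full pipeline: simulate, train, screen, evaluate
#'
#' Executes every stage end-to-end on synthetic data: genotype and cohort
#' simulation, data split, GWAS, polygenic score training and selection,
#' scoring, fracture-probability surrogate, base and gSOS-gated screening,
#' and the performance comparison. Deterministic given the configuration:
#' per-stage seeds are derived from `config$seed`.
#'
#' @param config A configuration list ([default_config()] / [read_config()]).
#' @param out_dir Optional directory; if given, the cohort, GWAS table, model
#'   files, traces and JSON reports are written there.
#' @return Invisible list with the cohort, split, `gwas`, fitted `model`,
#'   traces, reports and `comparison`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  g <- config$genotypes
  panel <- simulate_genotypes(g$n_individuals, g$n_snps,
                              maf_range = g$maf_range,
                              block_size = g$block_size,
                              block_rho = g$block_rho,
                              seed = .child_seed(seed, "genotypes"))
  rf <- simulate_risk_factors(g$n_individuals,
                              age_range = config$risk_factors$age_range,
                              female_fraction = config$risk_factors$female_fraction,
                              seed = .child_seed(seed, "risk_factors"))
  ph <- simulate_phenotypes(panel, n_causal = config$phenotypes$n_causal,
                            h2_sos = config$phenotypes$h2_sos,
                            sos_bmd_corr = config$phenotypes$sos_bmd_corr,
                            age = rf$age, sex = rf$sex,
                            seed = .child_seed(seed, "phenotypes"))
  cohort <- assemble_cohort(rf, ph)

  split <- split_cohort(g$n_individuals, config$split$fractions,
                        seed = .child_seed(seed, "split"))
  covars <- cbind(age = cohort$age, female = as.numeric(cohort$sex == "female"))
  gwas <- run_gwas(panel, cohort$sos_std, covars, subset = split$training)
  model <- prs_fit(panel, cohort$sos_std, split, covariates = covars,
                   gwas = gwas,
                   p_thresholds = config$prs$p_thresholds,
                   n_lambda = config$prs$n_lambda,
                   lambda_min_ratio = config$prs$lambda_min_ratio)
  cohort$gsos <- predict(model, panel)

  frax <- do.call(frax_params, config$frax_surrogate)
  cfg_base <- nogg_config(gsos_threshold_male = Inf,
                          gsos_threshold_female = Inf)
  cfg_gate <- nogg_config(
    gsos_threshold_male = config$screening$gsos_threshold_male,
    gsos_threshold_female = config$screening$gsos_threshold_female,
    gate_placement = config$screening$gate_placement)

  test_cohort <- cohort[split$test, , drop = FALSE]
  base_tr <- nogg_screen(test_cohort, frax, cfg_base)
  gate_tr <- gsos_nogg_screen(test_cohort, frax, cfg_gate)
  ref <- reference_standard(test_cohort, frax, cfg_base)
  base_rep <- performance_report(base_tr, ref, config = cfg_base)
  gate_rep <- performance_report(gate_tr, ref, config = cfg_gate)
  cmp <- compare_strategies(base_rep, gate_rep)

  res <- list(config = config, cohort = cohort, split = split, gwas = gwas,
              model = model, base_traces = base_tr, gated_traces = gate_tr,
              reference = ref, base_report = base_rep,
              gated_report = gate_rep, comparison = cmp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    write.table(gwas, file.path(out_dir, "gwas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_prs_model(model, file.path(out_dir, "prs_model.tsv"))
    write.table(base_tr, file.path(out_dir, "traces_base.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(gate_tr, file.path(out_dir, "traces_gated.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    reports <- list(
      seed = seed,
      base = unclass(base_rep)[setdiff(names(base_rep), "config")],
      gated = unclass(gate_rep)[setdiff(names(gate_rep), "config")],
      comparison = unclass(cmp))
    jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
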