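#' Configuration of the staged (NOGG-style) screening algorithm
#'
#' @param min_age Eligibility age floor in years (default 50).
#' @param upper_assessment_multiplier High-risk cutoff after CRF-FRAX, as a
#'   multiple of the age-specific intervention threshold (default 1.2).
#' @param lower_assessment_rule How the reassurance cutoff after CRF-FRAX is
#'   formed: `"reference-woman-no-crf"` (default; the CRF-FRAX of a same-age
#'   reference woman with no risk factors) or `"multiplier"` (a multiple of
#'   the intervention threshold, see `lower_assessment_multiplier`).
#' @param lower_assessment_multiplier Used when
#'   `lower_assessment_rule = "multiplier"` (e.g. 0.5).
#' @param gsos_threshold_male,gsos_threshold_female Standardized gSOS gate
#'   thresholds: individuals with gSOS strictly above their sex's threshold
#'   are reassured without further testing (defaults 0.5 and 0; `Inf`
#'   disables the gate).
#' @param gate_placement `"before_crf"` (default; the gate precedes all FRAX
#'   testing) or `"after_crf"` (the gate applies only to individuals left at
#'   intermediate risk by CRF-FRAX, i.e. it removes BMD-FRAX tests only).
#' @param auto_treat_women_prior_fracture Women at or above `min_age` with a
#'   prior fragility fracture are recommended treatment without any FRAX
#'   testing (default `TRUE`); this precedes the gSOS gate.
#' @return An object of class `nogg_config`.
#' @export
nogg_config <- function(min_age = 50,
                        upper_assessment_multiplier = 1.2,
                        lower_assessment_rule = c("reference-woman-no-crf",
                                                  "multiplier"),
                        lower_assessment_multiplier = 0.5,
                        gsos_threshold_male = 0.5,
                        gsos_threshold_female = 0,
                        gate_placement = c("before_crf", "after_crf"),
                        auto_treat_women_prior_fracture = TRUE) {
  if (upper_assessment_multiplier <= 0 || lower_assessment_multiplier <= 0)
    .stopf("assessment multipliers must be positive")
  if (is.na(gsos_threshold_male) || is.na(gsos_threshold_female))
    .stopf("gSOS thresholds must be finite or +/-Inf")
  structure(list(
    min_age = min_age,
    upper_assessment_multiplier = upper_assessment_multiplier,
    lower_assessment_rule = match.arg(lower_assessment_rule),
    lower_assessment_multiplier = lower_assessment_multiplier,
    gsos_thresholds = c(male = gsos_threshold_male,
                        female = gsos_threshold_female),
    gate_placement = match.arg(gate_placement),
    auto_treat_women_prior_fracture = auto_treat_women_prior_fracture
  ), class = "nogg_config")
}

#' @export
print.nogg_config <- function(x, ...) {
  cat("NOGG-style screening configuration\n")
  cat(sprintf("  eligibility: age >= %g, >= 1 risk factor, BMD T-score present\n",
              x$min_age))
  cat(sprintf("  assessment band: treat if CRF-FRAX >= %.2f x IT; reassure below the %s rule\n",
              x$upper_assessment_multiplier,
              if (x$lower_assessment_rule == "multiplier")
                sprintf("%.2f x IT", x$lower_assessment_multiplier)
              else "reference-woman"))
  cat(sprintf("  gSOS gate (%s): male > %g, female > %g -> reassure; auto-treat women with prior fracture: %s\n",
              x$gate_placement, x$gsos_thresholds["male"],
              x$gsos_thresholds["female"],
              x$auto_treat_women_prior_fracture))
  invisible(x)
}

#' Screening eligibility
#'
#' An individual is eligible for the screening program if aged at least
#' `min_age`, with at least one binary FRAX clinical risk factor, and with a
#' femoral-neck BMD T-score available (required so the BMD-FRAX reference
#' standard can be evaluated).
#'
#' @param cohort Cohort `data.frame`.
#' @param config A [nogg_config()].
#' @return Logical vector.
#' @export
is_eligible <- function(cohort, config = nogg_config()) {
  miss <- setdiff(c("age", "sex", .risk_factor_names), names(cohort))
  if (length(miss)) .stopf("cohort is missing field(s): %s",
                           paste(miss, collapse = ", "))
  rf <- as.matrix(cohort[.risk_factor_names])
  if (anyNA(rf)) .stopf("missing values in risk-factor fields")
  has_t <- if (is.null(cohort$fn_bmd_tscore)) rep(FALSE, nrow(cohort))
           else !is.na(cohort$fn_bmd_tscore)
  cohort$age >= config$min_age & rowSums(rf) >= 1 & has_t
}

.lower_threshold <- function(age, frax, config) {
  if (config$lower_assessment_rule == "multiplier")
    config$lower_assessment_multiplier * intervention_threshold(age, frax)
  else lower_assessment_threshold(age, frax)
}

## Shared decision engine for the base and gSOS-gated strategies. Vectorized;
## returns one trace row per cohort row (ineligible rows -> "not_screened").
.screen_engine <- function(cohort, frax, config, gated) {
  n <- nrow(cohort)
  elig <- is_eligible(cohort, config)
  sexes <- as.character(cohort$sex)

  tr <- data.frame(
    id = cohort$id %||% sprintf("row%06d", seq_len(n)),
    eligible = elig,
    excluded_by_gsos = rep(FALSE, n),
    auto_treated = rep(FALSE, n),
    crf_frax_done = rep(FALSE, n),
    crf_frax_value = rep(NA_real_, n),
    risk_band = rep(NA_character_, n),
    bmd_frax_done = rep(FALSE, n),
    bmd_frax_value = rep(NA_real_, n),
    recommendation = ifelse(elig, NA_character_, "not_screened"),
    stringsAsFactors = FALSE
  )

  gsos <- cohort$gsos
  if (gated) {
    if (is.null(gsos)) .stopf("gated screening requires a `gsos` column")
    if (any(elig & is.na(gsos))) .stopf("missing gsos for eligible individual(s)")
    thr <- unname(config$gsos_thresholds[sexes])
  }

  ## 1. auto-treatment of women >= min_age with a prior fragility fracture
  ##    (precedes the gate: the reference standard also treats them)
  auto <- elig & config$auto_treat_women_prior_fracture &
    sexes == "female" & cohort$age >= config$min_age & cohort$prior_fracture
  tr$auto_treated[auto] <- TRUE
  tr$recommendation[auto] <- "treat"

  ## 2. gSOS gate before any FRAX testing
  pend <- elig & !auto
  if (gated && config$gate_placement == "before_crf") {
    out <- pend & gsos > thr
    tr$excluded_by_gsos[out] <- TRUE
    tr$recommendation[out] <- "reassure"
    pend <- pend & !out
  }

  ## 3. CRF-FRAX triage into high / intermediate / low bands
  if (any(pend)) {
    sub <- cohort[pend, , drop = FALSE]
    crf <- crf_frax(sub, frax)
    it <- intervention_threshold(sub$age, frax)
    hi <- crf >= config$upper_assessment_multiplier * it
    lo <- crf < .lower_threshold(sub$age, frax, config)
    lo <- lo & !hi
    band <- ifelse(hi, "high", ifelse(lo, "low", "intermediate"))
    tr$crf_frax_done[pend] <- TRUE
    tr$crf_frax_value[pend] <- crf
    tr$risk_band[pend] <- band
    idx <- which(pend)
    tr$recommendation[idx[hi]] <- "treat"
    tr$recommendation[idx[lo]] <- "reassure"

    mid <- !hi & !lo
    ## 3b. gate placed immediately after CRF-FRAX: applies only to
    ##     individuals not already resolved by the CRF band
    if (gated && config$gate_placement == "after_crf") {
      gout <- mid & gsos[pend] > thr[pend]
      tr$excluded_by_gsos[idx[gout]] <- TRUE
      tr$recommendation[idx[gout]] <- "reassure"
      mid <- mid & !gout
    }

    ## 4. BMD-FRAX for the intermediate band; treat iff it reaches the
    ##    age-specific intervention threshold
    if (any(mid)) {
      sub2 <- sub[mid, , drop = FALSE]
      bmd <- bmd_frax(sub2, frax)
      tr$bmd_frax_done[idx[mid]] <- TRUE
      tr$bmd_frax_value[idx[mid]] <- bmd
      treat2 <- bmd >= it[mid]
      tr$recommendation[idx[mid]] <- ifelse(treat2, "treat", "reassure")
    }
  }
  class(tr) <- c("screening_trace", "data.frame")
  tr
}

#' Base NOGG-style screening strategy
#'
#' Staged screening: women at or above the age floor with a prior fragility
#' fracture are recommended treatment without testing; everyone else receives
#' a CRF-FRAX test and is triaged to treatment (high band), reassurance (low
#' band), or a BMD-FRAX test (intermediate band), where treatment is
#' recommended iff BMD-FRAX reaches the age-specific intervention threshold.
#'
#' @param cohort Cohort `data.frame` (may include ineligible rows; they are
#'   traced as `not_screened`).
#' @param frax A [frax_params()] object (ignored for individuals whose cohort
#'   rows already carry `crf_frax`/`bmd_frax` columns).
#' @param config A [nogg_config()].
#' @return A `data.frame` of class `screening_trace`, one row per individual:
#'   tests consumed, band, values, and final `recommendation`
#'   (`treat` / `reassure` / `not_screened`).
#' @export
nogg_screen <- function(cohort, frax = frax_params(), config = nogg_config()) {
  .screen_engine(cohort, frax, config, gated = FALSE)
}

#' NOGG-style screening with a gSOS pre-screening gate
#'
#' As [nogg_screen()], but individuals whose standardized genetic score
#' (`gsos` column) lies strictly above their sex-specific threshold are
#' reassured without further testing. With
#' `gate_placement = "after_crf"` the gate instead applies only to
#' individuals left at intermediate risk by CRF-FRAX. Auto-treatment of women
#' with a prior fragility fracture precedes the gate in both placements.
#'
#' @inheritParams nogg_screen
#' @return A `screening_trace` data frame.
#' @export
gsos_nogg_screen <- function(cohort, frax = frax_params(),
                             config = nogg_config()) {
  .screen_engine(cohort, frax, config, gated = TRUE)
}

#' BMD-FRAX reference standard for correct treatment assignment
#'
#' The reference recommendation against which screening strategies are judged:
#' treat iff BMD-FRAX reaches the age-specific intervention threshold, or the
#' individual is a woman at or above the age floor with a prior fragility
#' fracture (auto-assigned an intervention); otherwise reassure. Only defined
#' for eligible individuals (`NA` otherwise).
#'
#' @inheritParams nogg_screen
#' @return Character vector (`"treat"` / `"reassure"`, `NA` if ineligible)
#'   named by individual id.
#' @export
reference_standard <- function(cohort, frax = frax_params(),
                               config = nogg_config()) {
  elig <- is_eligible(cohort, config)
  out <- rep(NA_character_, nrow(cohort))
  if (any(elig)) {
    sub <- cohort[elig, , drop = FALSE]
    if (anyNA(sub$fn_bmd_tscore)) .stopf("missing T-score in eligible rows")
    auto <- config$auto_treat_women_prior_fracture &
      as.character(sub$sex) == "female" & sub$age >= config$min_age &
      sub$prior_fracture
    treat <- auto | bmd_frax(sub, frax) >= intervention_threshold(sub$age, frax)
    out[elig] <- ifelse(treat, "treat", "reassure")
  }
  names(out) <- cohort$id %||% sprintf("row%06d", seq_len(nrow(cohort)))
  out
}
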