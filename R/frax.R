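#' Parameters of the parametric FRAX-style fracture-probability surrogate
#'
#' The surrogate maps clinical risk factors (and optionally a femoral-neck BMD
#' T-score) to a 10-year probability of major osteoporotic fracture via a
#' complementary-log-log link on a Gompertz-like hazard:
#' \deqn{P = 100 (1 - e^{-H}), \quad
#'       H = s_{sex} \exp\{b (age - 50) + \sum_f \log RR_f x_f +
#'           \log RR_{BMI} (BMI - 25) + \log RR_{BMD} (T_c - T)\}}
#' where the BMD term is present only in the BMD-based score. At `T = t_center`
#' the two scores coincide, so `t_center` plays the role of the population
#' T-score implicitly assumed by the clinical-risk-factor-only score. FRAX
#' itself is proprietary; this surrogate is a transparent, monotone stand-in
#' whose outputs occupy the same scale, and all screening logic is agnostic to
#' how the probabilities were produced (externally computed probabilities can
#' be supplied as `crf_frax`/`bmd_frax` cohort columns instead).
#'
#' @param baseline_scale_female,baseline_scale_male Baseline 10-year hazard at
#'   age 50 for a reference individual (BMI 25, no risk factors).
#' @param baseline_age_slope Per-year log-hazard slope.
#' @param rr_prior_fracture,rr_smoking,rr_glucocorticoids,rr_rheumatoid_arthritis,rr_secondary_osteoporosis,rr_parental_hip_fracture,rr_alcohol
#'   Relative risks (all `>= 1`) for the binary clinical risk factors.
#' @param rr_bmi_per_unit Relative risk per BMI unit above 25 (in (0, 1):
#'   higher BMI is protective).
#' @param rr_bmd_per_t Relative risk per T-score unit below `t_center` (`> 1`).
#' @param t_center T-score at which the BMD-based score equals the
#'   clinical-risk-factor score.
#' @param age_domain Ages over which the surrogate is defined; inputs outside
#'   are clamped with a warning.
#' @param missing_as_no If `TRUE`, missing binary risk factors are treated as
#'   absent (the convention used when a cohort lacks a field); if `FALSE`
#'   (default) a missing field is an error.
#' @return An object of class `frax_params`.
#' @export
frax_params <- function(baseline_scale_female = 0.034,
                        baseline_scale_male = 0.023,
                        baseline_age_slope = 0.05,
                        rr_prior_fracture = 1.8,
                        rr_smoking = 1.25,
                        rr_glucocorticoids = 1.6,
                        rr_rheumatoid_arthritis = 1.3,
                        rr_secondary_osteoporosis = 1.35,
                        rr_parental_hip_fracture = 1.5,
                        rr_alcohol = 1.4,
                        rr_bmi_per_unit = 0.97,
                        rr_bmd_per_t = 1.6,
                        t_center = -1,
                        age_domain = c(50, 90),
                        missing_as_no = FALSE) {
  rr <- c(prior_fracture = rr_prior_fracture, smoking = rr_smoking,
          glucocorticoids = rr_glucocorticoids,
          rheumatoid_arthritis = rr_rheumatoid_arthritis,
          secondary_osteoporosis = rr_secondary_osteoporosis,
          parental_hip_fracture = rr_parental_hip_fracture,
          alcohol = rr_alcohol)
  if (any(rr < 1)) .stopf("risk-factor relative risks must be >= 1")
  if (baseline_scale_female <= 0 || baseline_scale_male <= 0)
    .stopf("baseline scales must be positive")
  if (rr_bmi_per_unit <= 0 || rr_bmi_per_unit >= 1)
    .stopf("`rr_bmi_per_unit` must lie in (0, 1)")
  if (rr_bmd_per_t <= 1) .stopf("`rr_bmd_per_t` must exceed 1")
  structure(list(
    baseline_scale = c(female = baseline_scale_female,
                       male = baseline_scale_male),
    baseline_age_slope = baseline_age_slope,
    log_rr = log(rr),
    log_rr_bmi = log(rr_bmi_per_unit),
    log_rr_bmd_per_t = log(rr_bmd_per_t),
    t_center = t_center,
    age_domain = age_domain,
    missing_as_no = missing_as_no
  ), class = "frax_params")
}

#' @export
print.frax_params <- function(x, ...) {
  cat("FRAX-style surrogate parameters\n")
  cat(sprintf("  baseline hazard at 50: female %.4f, male %.4f; age slope %.3f/yr\n",
              x$baseline_scale["female"], x$baseline_scale["male"],
              x$baseline_age_slope))
  cat(sprintf("  RR per factor: %s\n",
              paste(sprintf("%s %.2f", names(x$log_rr), exp(x$log_rr)),
                    collapse = ", ")))
  cat(sprintf("  RR per BMI unit %.2f; RR per T-score unit %.2f (t_center %.1f)\n",
              exp(x$log_rr_bmi), exp(x$log_rr_bmd_per_t), x$t_center))
  invisible(x)
}

.frax_clamp_age <- function(age, params) {
  lo <- params$age_domain[1]; hi <- params$age_domain[2]
  if (any(age < lo | age > hi, na.rm = TRUE)) {
    warning(sprintf("%d age value(s) outside [%g, %g] clamped to the domain",
                    sum(age < lo | age > hi, na.rm = TRUE), lo, hi),
            call. = FALSE)
    age <- pmin(pmax(age, lo), hi)
  }
  age
}

.frax_linpred <- function(cohort, params) {
  need <- c("age", "sex", "bmi", .risk_factor_names)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) .stopf("cohort is missing required field(s): %s",
                           paste(miss, collapse = ", "))
  sex <- as.character(cohort$sex)
  if (!all(sex %in% c("female", "male")))
    .stopf("`sex` must be 'female' or 'male'")
  age <- .frax_clamp_age(cohort$age, params)
  if (anyNA(age) || anyNA(cohort$bmi)) .stopf("missing `age` or `bmi`")
  lp <- log(params$baseline_scale[sex]) +
    params$baseline_age_slope * (age - 50) +
    params$log_rr_bmi * (cohort$bmi - 25)
  for (f in .risk_factor_names) {
    x <- cohort[[f]]
    if (anyNA(x)) {
      if (params$missing_as_no) x[is.na(x)] <- FALSE
      else .stopf("missing values in risk factor `%s`", f)
    }
    lp <- lp + params$log_rr[[f]] * as.numeric(x)
  }
  unname(lp)
}

#' Clinical-risk-factor FRAX surrogate (CRF-FRAX)
#'
#' 10-year probability (percent) of major osteoporotic fracture from clinical
#' risk factors only. Vectorized over cohort rows.
#'
#' @param cohort A cohort `data.frame` (rows are individuals) with `age`,
#'   `sex`, `bmi` and the binary risk-factor columns.
#' @param params A [frax_params()] object.
#' @return Numeric vector of probabilities in (0, 100).
#' @export
crf_frax <- function(cohort, params = frax_params()) {
  stopifnot(inherits(params, "frax_params"))
  if (!is.null(cohort$crf_frax)) return(as.numeric(cohort$crf_frax))
  H <- exp(.frax_linpred(cohort, params))
  100 * (1 - exp(-H))
}

#' BMD-based FRAX surrogate (BMD-FRAX)
#'
#' As [crf_frax()] with an additional multiplicative hazard term
#' `rr_bmd_per_t^(t_center - T)` for the femoral-neck BMD T-score `T`, so risk
#' increases as the T-score falls and the score equals CRF-FRAX at
#' `T = t_center`.
#'
#' @inheritParams crf_frax
#' @return Numeric vector of probabilities in (0, 100).
#' @export
bmd_frax <- function(cohort, params = frax_params()) {
  stopifnot(inherits(params, "frax_params"))
  if (!is.null(cohort$bmd_frax)) return(as.numeric(cohort$bmd_frax))
  t <- cohort$fn_bmd_tscore
  if (is.null(t) || anyNA(t)) .stopf("missing `fn_bmd_tscore` required for BMD-FRAX")
  H <- exp(.frax_linpred(cohort, params) +
             params$log_rr_bmd_per_t * (params$t_center - t))
  100 * (1 - exp(-H))
}

.reference_woman <- function(age, prior_fracture = FALSE) {
  out <- data.frame(age = age, sex = "female", bmi = 25,
                    stringsAsFactors = FALSE)
  for (f in .risk_factor_names) out[[f]] <- FALSE
  out$prior_fracture <- prior_fracture
  out
}

#' Age-specific intervention threshold
#'
#' The NOGG-style intervention threshold: the CRF-FRAX probability of a woman
#' of the same age whose only risk factor is a prior fragility fracture
#' (BMI 25), since nearly all such women would be recommended an intervention.
#' Non-decreasing in age.
#'
#' @param age Numeric vector of ages (years).
#' @param params A [frax_params()] object.
#' @return Numeric vector of threshold probabilities (percent).
#' @export
intervention_threshold <- function(age, params = frax_params()) {
  crf_frax(.reference_woman(age, prior_fracture = TRUE), params)
}

#' Lower (reassurance) assessment threshold
#'
#' CRF-FRAX probability of a same-age reference woman with no risk factors
#' (BMI 25); individuals below it are reassured without BMD testing.
#'
#' @inheritParams intervention_threshold
#' @return Numeric vector of threshold probabilities (percent).
#' @export
lower_assessment_threshold <- function(age, params = frax_params()) {
  crf_frax(.reference_woman(age, prior_fracture = FALSE), params)
}
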