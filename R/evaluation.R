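#' Performance of a screening strategy against the reference standard
#'
#' Confusion counts and screening-test burden of a strategy's decision traces,
#' judged against the BMD-FRAX-based reference standard. "Positive" means the
#' reference recommends treatment; a trace's prediction is positive iff its
#' recommendation is `treat` (individuals excluded by the gSOS gate therefore
#' count as predicted reassure). Only eligible individuals enter any
#' denominator. Ratios with an empty denominator are reported as `NA` and
#' listed in `$undefined`, never as 0.
#'
#' @param traces A `screening_trace` data frame ([nogg_screen()] /
#'   [gsos_nogg_screen()]).
#' @param reference Named character vector (`id -> "treat"/"reassure"`) as
#'   returned by [reference_standard()], or a data.frame with `id` and
#'   `reference` columns.
#' @param config Optional configuration object(s) to snapshot into the report.
#' @return An object of class `performance_report`: counts `tp fp fn tn`,
#'   `n_eligible`, percentages `sensitivity specificity ppv npv`,
#'   test-burden percentages `pct_crf_tested pct_bmd_tested` (of eligible) and
#'   `pct_crf_reassured pct_bmd_reassured` (tests whose subject ended
#'   reassured, as a percentage of that test's count), plus `undefined` flags
#'   and the `config` snapshot.
#' @export
performance_report <- function(traces, reference, config = NULL) {
  if (is.data.frame(reference)) {
    reference <- setNames(as.character(reference$reference), reference$id)
  }
  el <- traces[traces$eligible, , drop = FALSE]
  ref <- reference[match(el$id, names(reference))]
  if (anyNA(match(el$id, names(reference))))
    .stopf("reference standard missing for %d eligible id(s)",
           sum(is.na(match(el$id, names(reference)))))
  if (anyNA(ref)) .stopf("reference standard is NA for eligible id(s)")

  pos <- ref == "treat"
  pred <- el$recommendation == "treat"
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  n <- nrow(el)

  undefined <- character(0)
  pct <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(NA_real_) }
    100 * num / den
  }
  crf_n <- sum(el$crf_frax_done)
  bmd_n <- sum(el$bmd_frax_done)
  out <- list(
    tp = tp, fp = fp, fn = fn, tn = tn, n_eligible = n,
    sensitivity = pct(tp, tp + fn, "sensitivity"),
    specificity = pct(tn, tn + fp, "specificity"),
    ppv = pct(tp, tp + fp, "ppv"),
    npv = pct(tn, tn + fn, "npv"),
    n_crf_tested = crf_n, n_bmd_tested = bmd_n,
    pct_crf_tested = pct(crf_n, n, "pct_crf_tested"),
    pct_bmd_tested = pct(bmd_n, n, "pct_bmd_tested"),
    pct_crf_reassured = pct(sum(el$crf_frax_done &
                                  el$recommendation == "reassure"),
                            crf_n, "pct_crf_reassured"),
    pct_bmd_reassured = pct(sum(el$bmd_frax_done &
                                  el$recommendation == "reassure"),
                            bmd_n, "pct_bmd_reassured"),
    config = config
  )
  out$undefined <- undefined
  class(out) <- "performance_report"
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Screening performance on %d eligible individuals\n", x$n_eligible))
  cat(sprintf("  confusion: TP %d, FP %d, FN %d, TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("  sensitivity %s, specificity %s, PPV %s, NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  cat(sprintf("  CRF-FRAX tests: %s of eligible (%s ending in reassurance)\n",
              fmt(x$pct_crf_tested), fmt(x$pct_crf_reassured)))
  cat(sprintf("  BMD-FRAX tests: %s of eligible (%s ending in reassurance)\n",
              fmt(x$pct_bmd_tested), fmt(x$pct_bmd_reassured)))
  invisible(x)
}

#' Compare two screening strategies on the same cohort
#'
#' Relative reductions in screening-test burden of a variant strategy versus a
#' base strategy, plus absolute differences in the accuracy metrics. Relative
#' reduction is `100 * (1 - variant / base)` of the corresponding test
#' percentage; a reduction with a zero base is `NA` and flagged.
#'
#' @param base,variant `performance_report`s computed on the same cohort.
#' @return List with `rel_reduction_crf_pct`, `rel_reduction_bmd_pct`,
#'   `delta_sensitivity`, `delta_specificity`, `delta_ppv`, `undefined`.
#' @export
compare_strategies <- function(base, variant) {
  stopifnot(inherits(base, "performance_report"),
            inherits(variant, "performance_report"))
  if (base$n_eligible != variant$n_eligible)
    .stopf("reports cover different cohorts (%d vs %d eligible)",
           base$n_eligible, variant$n_eligible)
  undefined <- character(0)
  rel <- function(b, v, what) {
    if (is.na(b) || b == 0) { undefined <<- c(undefined, what); return(NA_real_) }
    100 * (1 - v / b)
  }
  out <- list(
    rel_reduction_crf_pct = rel(base$pct_crf_tested, variant$pct_crf_tested,
                                "rel_reduction_crf_pct"),
    rel_reduction_bmd_pct = rel(base$pct_bmd_tested, variant$pct_bmd_tested,
                                "rel_reduction_bmd_pct"),
    delta_sensitivity = variant$sensitivity - base$sensitivity,
    delta_specificity = variant$specificity - base$specificity,
    delta_ppv = variant$ppv - base$ppv,
    undefined = undefined
  )
  class(out) <- "strategy_comparison"
  out
}

#' @export
print.strategy_comparison <- function(x, ...) {
  fmt0 <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f%%", v)
  cat(sprintf("CRF-FRAX tests: relative reduction %s; BMD-FRAX tests: relative reduction %s\n",
              fmt0(x$rel_reduction_crf_pct), fmt0(x$rel_reduction_bmd_pct)))
  cat(sprintf("  sensitivity %+0.1f, specificity %+0.1f, PPV %+0.1f (percentage points)\n",
              x$delta_sensitivity, x$delta_specificity, x$delta_ppv))
  invisible(x)
}

#' Select sex-specific gSOS gate thresholds
#'
#' For each sex independently, evaluates the gated strategy over a grid of
#' candidate thresholds and returns, among thresholds whose within-sex
#' sensitivity stays at or above `min_sensitivity`, the one minimizing the
#' number of BMD-FRAX tests performed on individuals who end up reassured
#' (wasted BMD tests). Exact ties break toward the larger threshold (less
#' exclusion); if no threshold satisfies the constraint, `+Inf` (no gate) is
#' returned. A sex with no reference-positive individuals has an undefined
#' sensitivity, which is treated as satisfying the constraint.
#'
#' @param cohort Cohort `data.frame` with a `gsos` column.
#' @param frax A [frax_params()].
#' @param config A [nogg_config()] (its own thresholds are overridden during
#'   the sweep).
#' @param grid Numeric vector of candidate thresholds; must include `Inf`.
#' @param min_sensitivity Constraint in percent, in (0, 100].
#' @param per_sex Select thresholds separately by sex (default `TRUE`); if
#'   `FALSE` one common threshold is chosen on the pooled cohort and returned
#'   for both sexes.
#' @return Named numeric vector `c(female = ..., male = ...)`.
#' @export
select_gsos_thresholds <- function(cohort, frax = frax_params(),
                                   config = nogg_config(),
                                   grid = c(seq(-2, 2, by = 0.1), Inf),
                                   min_sensitivity = 90, per_sex = TRUE) {
  if (!length(grid)) .stopf("empty threshold grid")
  if (!any(is.infinite(grid) & grid > 0)) .stopf("grid must include +Inf")
  .assert_scalar_prob(min_sensitivity, "min_sensitivity", 0, 100,
                      open_lo = TRUE, open_hi = FALSE)
  grid <- sort(unique(grid))

  eval_group <- function(sub) {
    ref <- reference_standard(sub, frax, config)
    vapply(grid, function(t) {
      cfg <- config
      cfg$gsos_thresholds[] <- t
      rep <- performance_report(gsos_nogg_screen(sub, frax, cfg), ref)
      wasted <- if (rep$n_bmd_tested == 0) 0
                else rep$n_bmd_tested * rep$pct_bmd_reassured / 100
      c(sens = rep$sensitivity, wasted = wasted)
    }, numeric(2))
  }

  pick <- function(sub) {
    m <- eval_group(sub)
    sens <- m["sens", ]
    wasted <- m["wasted", ]
    ok <- is.na(sens) | sens >= min_sensitivity
    if (!any(ok)) return(Inf)
    cand <- which(ok)
    grid[cand[order(wasted[cand], -grid[cand])][1]]
  }

  if (!per_sex) {
    t0 <- pick(cohort)
    return(c(female = t0, male = t0))
  }
  sexes <- as.character(cohort$sex)
  c(female = pick(cohort[sexes == "female", , drop = FALSE]),
    male = pick(cohort[sexes == "male", , drop = FALSE]))
}

#' Stratified performance reports
#'
#' Recomputes base/variant performance and their comparison within strata
#' (sex, or age bands), using only the stratum's members in every denominator.
#' Decision traces are per-individual, so subsetting precomputed traces is
#' exact.
#'
#' @param cohort Cohort `data.frame`.
#' @param base_traces,variant_traces `screening_trace` data frames for the
#'   whole cohort.
#' @param reference Named reference-standard vector for the whole cohort.
#' @param strata `"sex"` or `"age_band"`.
#' @param age_breaks Left-closed age band edges (default 50, 60, 70, Inf).
#' @return Named list of strata, each a list with `base`, `variant`
#'   (`performance_report`s, flagged `empty = TRUE` if the stratum has no
#'   eligible members) and `comparison`.
#' @export
stratified_reports <- function(cohort, base_traces, variant_traces, reference,
                               strata = c("sex", "age_band"),
                               age_breaks = c(50, 60, 70, Inf)) {
  strata <- match.arg(strata)
  lab <- if (strata == "sex") {
    as.character(cohort$sex)
  } else {
    brk <- age_breaks
    labels <- paste0(brk[-length(brk)], "-", c(brk[-c(1, length(brk))] - 1, ""))
    labels[length(labels)] <- paste0(">=", brk[length(brk) - 1])
    as.character(cut(cohort$age, breaks = brk, labels = labels, right = FALSE))
  }
  out <- list()
  for (s in sort(unique(lab[!is.na(lab)]))) {
    rows <- which(lab == s)
    ids <- base_traces$id[rows]
    bt <- base_traces[rows, , drop = FALSE]
    vt <- variant_traces[rows, , drop = FALSE]
    if (!any(bt$eligible)) {
      out[[s]] <- list(empty = TRUE)
      next
    }
    b <- performance_report(bt, reference[names(reference) %in% ids])
    v <- performance_report(vt, reference[names(reference) %in% ids])
    out[[s]] <- list(base = b, variant = v, comparison = compare_strategies(b, v))
  }
  out
}
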