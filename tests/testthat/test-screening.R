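test_that("eligibility requires age 50+, one risk factor, and a T-score", {
  ok <- make_person(age = 62, prior_fracture = TRUE)
  expect_true(is_eligible(ok))
  young <- make_person(age = 49, sex = "male", smoking = TRUE)
  expect_false(is_eligible(young))
  nofactor <- make_person(age = 70)
  expect_false(is_eligible(nofactor))
  not <- make_person(age = 70, smoking = TRUE)
  not$fn_bmd_tscore <- NA
  expect_false(is_eligible(not))
  broken <- make_person(age = 70); broken$smoking <- NULL
  expect_error(is_eligible(broken), "smoking")
})

test_that("women 50+ with a prior fragility fracture are treated without testing", {
  frax <- frax_params()
  w <- make_person(age = 65, prior_fracture = TRUE)
  tr <- nogg_screen(w, frax)
  expect_identical(tr$recommendation, "treat")
  expect_true(tr$auto_treated)
  expect_false(tr$crf_frax_done)
  expect_false(tr$bmd_frax_done)
  # identical woman but male: no auto-treatment
  m <- make_person(age = 65, sex = "male", prior_fracture = TRUE)
  trm <- nogg_screen(m, frax)
  expect_true(trm$crf_frax_done)
  # auto-treatment can be configured off
  tr2 <- nogg_screen(w, frax, nogg_config(auto_treat_women_prior_fracture = FALSE))
  expect_true(tr2$crf_frax_done)
})

test_that("CRF bands route to treat / reassure / BMD testing as configured", {
  frax <- frax_params()
  cfg <- nogg_config()
  # a man with many factors at high age: CRF >= 1.2 x IT -> treat, CRF only
  hi <- make_person(age = 85, sex = "male", bmi = 18, prior_fracture = TRUE,
                    glucocorticoids = TRUE, smoking = TRUE, alcohol = TRUE,
                    rheumatoid_arthritis = TRUE)
  expect_gte(crf_frax(hi, frax), 1.2 * intervention_threshold(85, frax))
  tr <- nogg_screen(hi, frax, cfg)
  expect_identical(tr$risk_band, "high")
  expect_identical(tr$recommendation, "treat")
  expect_false(tr$bmd_frax_done)
  # a man with one weak factor and high BMI: below the reference-woman curve
  lo <- make_person(age = 60, sex = "male", bmi = 32, smoking = TRUE)
  expect_lt(crf_frax(lo, frax), lower_assessment_threshold(60, frax))
  trl <- nogg_screen(lo, frax, cfg)
  expect_identical(trl$risk_band, "low")
  expect_identical(trl$recommendation, "reassure")
  expect_false(trl$bmd_frax_done)
  # intermediate: BMD-FRAX decides against IT, here a protective T-score
  mid <- make_person(age = 60, sex = "male", prior_fracture = TRUE, tscore = 1)
  trm <- nogg_screen(mid, frax, cfg)
  expect_identical(trm$risk_band, "intermediate")
  expect_true(trm$bmd_frax_done)
  expect_identical(trm$recommendation, "reassure")
  expect_lt(trm$bmd_frax_value, intervention_threshold(60, frax))
  # same person with a very low T-score is treated after BMD-FRAX
  mid$fn_bmd_tscore <- -3.5
  trt <- nogg_screen(mid, frax, cfg)
  expect_true(trt$bmd_frax_done)
  expect_identical(trt$recommendation, "treat")
})

test_that("the gSOS gate reassures high-score individuals with zero tests", {
  frax <- frax_params()
  m <- make_person(age = 70, sex = "male", smoking = TRUE, gsos = 0.7)
  tr <- gsos_nogg_screen(m, frax)
  expect_identical(tr$recommendation, "reassure")
  expect_true(tr$excluded_by_gsos)
  expect_false(tr$crf_frax_done)
  expect_false(tr$bmd_frax_done)
  # at the threshold (not above) the gate does not fire
  m$gsos <- 0.5
  expect_false(gsos_nogg_screen(m, frax)$excluded_by_gsos)
  # auto-treatment precedes the gate
  w <- make_person(age = 66, prior_fracture = TRUE, gsos = 2)
  trw <- gsos_nogg_screen(w, frax)
  expect_identical(trw$recommendation, "treat")
  expect_true(trw$auto_treated)
  expect_false(trw$excluded_by_gsos)
  expect_error(gsos_nogg_screen(make_person(age = 60, smoking = TRUE), frax),
               "gsos")
})

test_that("gate at +Inf reproduces the base strategy trace-for-trace", {
  ch <- shared_screening_cohort()
  frax <- frax_params()
  cfg <- nogg_config(gsos_threshold_male = Inf, gsos_threshold_female = Inf)
  base <- nogg_screen(ch, frax, cfg)
  gated <- gsos_nogg_screen(ch, frax, cfg)
  expect_identical(base, gated)
})

test_that("gate placement after CRF-FRAX only removes BMD tests", {
  ch <- shared_screening_cohort()[1:3000, ]
  frax <- frax_params()
  before <- gsos_nogg_screen(ch, frax, nogg_config(gate_placement = "before_crf"))
  after <- gsos_nogg_screen(ch, frax, nogg_config(gate_placement = "after_crf"))
  base <- nogg_screen(ch, frax)
  # after-CRF gating: CRF testing identical to base, BMD testing reduced
  expect_identical(after$crf_frax_done, base$crf_frax_done)
  expect_lt(sum(after$bmd_frax_done), sum(base$bmd_frax_done))
  expect_gt(sum(after$crf_frax_done), sum(before$crf_frax_done))
  # gated-out individuals after CRF are intermediates who got no BMD test
  out <- after$excluded_by_gsos
  expect_true(all(after$risk_band[out] == "intermediate"))
  expect_true(all(!after$bmd_frax_done[out]))
  expect_true(all(after$recommendation[out] == "reassure"))
})

test_that("traces never violate their structural invariants", {
  ch <- shared_screening_cohort()
  # append some ineligible rows
  extra <- simulate_risk_factors(500, age_range = c(30, 49), seed = 91)
  extra$fn_bmd_tscore <- rnorm(500); extra$sos_std <- rnorm(500)
  extra$gsos <- rnorm(500)
  extra$id <- paste0("x", extra$id)
  ch2 <- rbind(ch, extra[names(ch)])
  frax <- frax_params()
  for (cfg in list(nogg_config(),
                   nogg_config(gate_placement = "after_crf"),
                   nogg_config(auto_treat_women_prior_fracture = FALSE))) {
    tr <- gsos_nogg_screen(ch2, frax, cfg)
    expect_true(all(tr$recommendation[!tr$eligible] == "not_screened"))
    expect_true(all(tr$recommendation[tr$eligible] %in% c("treat", "reassure")))
    # BMD test implies CRF test (auto-treated have neither)
    expect_true(all(tr$crf_frax_done[tr$bmd_frax_done]))
    expect_true(all(!tr$crf_frax_done[tr$auto_treated]))
    expect_true(all(tr$recommendation[tr$auto_treated] == "treat"))
    # excluded by gate: reassured, and no tests after the gate
    out <- tr$excluded_by_gsos
    expect_true(all(tr$recommendation[out] == "reassure"))
    expect_true(all(!tr$bmd_frax_done[out]))
    # high band treated with CRF at or above the upper threshold
    hi <- which(tr$risk_band == "high")
    expect_true(all(tr$crf_frax_value[hi] >=
      cfg$upper_assessment_multiplier *
        intervention_threshold(ch2$age[hi], frax)))
    expect_true(all(tr$recommendation[hi] == "treat"))
    # value fields present exactly when the test was done
    expect_true(all(is.na(tr$crf_frax_value) != tr$crf_frax_done))
    expect_true(all(is.na(tr$bmd_frax_value) != tr$bmd_frax_done))
  }
})

test_that("reference standard treats auto-treat women and low-BMD individuals", {
  frax <- frax_params()
  w <- make_person(age = 58, prior_fracture = TRUE, tscore = 1.5)
  expect_identical(unname(reference_standard(w, frax)), "treat")
  # exact boundary: BMD-FRAX equal to IT counts as treat. The reference woman
  # with a prior fracture at T = t_center has BMD-FRAX identical to IT by
  # construction; disable auto-treatment to exercise the comparison itself.
  cfg <- nogg_config(auto_treat_women_prior_fracture = FALSE)
  b <- make_person(age = 66, prior_fracture = TRUE, tscore = frax$t_center)
  expect_identical(unname(reference_standard(b, frax, cfg)), "treat")
  b$fn_bmd_tscore <- frax$t_center + 0.2
  expect_identical(unname(reference_standard(b, frax, cfg)), "reassure")
  nf <- make_person(age = 70)
  expect_identical(unname(reference_standard(nf, frax)), NA_character_)
})
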