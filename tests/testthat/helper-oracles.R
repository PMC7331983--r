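# Independent oracles used across tests. Deliberately naive (scalar loops,
# brute force) so they share no code with the implementation they check.

# Scalar re-evaluation of the fracture-probability closed form for one person.
frax_oracle_row <- function(row, params, with_bmd = FALSE) {
  s <- if (row$sex == "female") params$baseline_scale[["female"]]
       else params$baseline_scale[["male"]]
  lp <- log(s) + params$baseline_age_slope * (row$age - 50) +
    params$log_rr_bmi * (row$bmi - 25)
  for (f in risk_factor_names())
    if (isTRUE(row[[f]])) lp <- lp + params$log_rr[[f]]
  if (with_bmd)
    lp <- lp + params$log_rr_bmd_per_t * (params$t_center - row$fn_bmd_tscore)
  100 * (1 - exp(-exp(lp)))
}

# Brute-force greedy LD clumping on a precomputed correlation matrix.
clump_oracle <- function(p, R2, r2_max, p_max) {
  avail <- which(p <= p_max)
  picked <- integer(0)
  while (length(avail)) {
    i <- avail[order(p[avail], avail)][1]
    picked <- c(picked, i)
    avail <- avail[R2[i, avail] <= r2_max]
  }
  picked
}

# Tiny cohort rows for screening edge cases.
make_person <- function(age = 60, sex = "female", bmi = 25, tscore = -1,
                        gsos = NA_real_, id = "p1", ...) {
  out <- data.frame(id = id, age = age, sex = sex, bmi = bmi,
                    fn_bmd_tscore = tscore, gsos = gsos,
                    stringsAsFactors = FALSE)
  for (f in risk_factor_names()) out[[f]] <- FALSE
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Default calibrated screening cohort shared by several expensive tests.
shared_screening_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_screening_cohort(10000, seed = 424242)
    cache
  }
})
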