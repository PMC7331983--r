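# gsosScreen

Polygenic pre-screening for osteoporotic fracture risk assessment.

Staged screening programs for osteoporosis (NOGG-style) triage with a
clinical-risk-factor FRAX probability (CRF-FRAX), send the intermediate-risk
band for bone-mineral-density measurement and a BMD-based FRAX (BMD-FRAX),
and treat when the 10-year probability of major osteoporotic fracture reaches
an age-specific intervention threshold IT(age) — the CRF-FRAX of a same-age
woman with a prior fragility fracture. Most tests end in reassurance. Heel
ultrasound speed of sound (SOS) is a heritable correlate of BMD, so a
polygenic score for SOS ("gSOS", standardized to mean 0, SD 1) can gate the
program: individuals with gSOS above a sex-specific threshold are reassured
before any FRAX testing, trading a bounded sensitivity loss for a large
reduction in test burden.

The package implements the full analysis on synthetic cohorts, for
biostatisticians and genetic epidemiologists studying genomics-enabled
screening:

* **Score training** — `prs_fit()` fits, for each GWAS p-value threshold in a
  grid, a LASSO path `min (2n)⁻¹‖y − Xβ‖² + λ‖β‖₁` over SNP dosages
  (coordinate descent in C++, warm starts), selects the (threshold, λ) pair
  with the lowest RMSE on a held-out model-selection set, and returns a
  classed `prs_model` with `print`/`summary`/`coef`/`predict`/`plot` methods.
  `traditional_prs()` provides the clump+threshold comparator;
  `run_gwas()`, `ld_clump()`, `split_cohort()`, `variance_explained()` the
  supporting steps.
* **Screening** — `nogg_screen()` and `gsos_nogg_screen()` produce a
  per-individual decision trace (tests consumed, risk band, recommendation)
  for the base and gated strategies; `reference_standard()` gives the
  BMD-FRAX-based reference; `frax_params()` parameterizes a transparent
  monotone surrogate `P = 100(1 − exp(−H))` for the proprietary FRAX
  calculator (externally computed probabilities are used verbatim when
  present as columns).
* **Evaluation** — `performance_report()`, `compare_strategies()`,
  `select_gsos_thresholds()`, `stratified_reports()` compute sensitivity /
  specificity / predictive values of correct treatment assignment,
  test-burden percentages, relative reductions, and sex-specific gate
  thresholds.
* **Synthetic cohorts** — `simulate_genotypes()` (LD-block latent-Gaussian
  dosages), `simulate_phenotypes()` (SOS with target heritability, BMD
  correlated after an age/sex trend), `simulate_risk_factors()`,
  `simulate_screening_cohort()`; plus TSV / PLINK-`.raw` / VCF IO and
  `run_pipeline()` to go end to end from one seeded config.

## Worked example

```r
library(gsosScreen)

ch   <- simulate_screening_cohort(10000, seed = 42)  # eligible, with gSOS
frax <- frax_params()
ref  <- reference_standard(ch, frax)

base  <- performance_report(nogg_screen(ch, frax), ref)
gated <- performance_report(gsos_nogg_screen(ch, frax), ref)
base; gated; compare_strategies(base, gated)
```

```
Screening performance on 10000 eligible individuals
  confusion: TP 3445, FP 36, FN 143, TN 6376
  sensitivity 96.0%, specificity 99.4%, PPV 99.0%, NPV 97.8%
  CRF-FRAX tests: 80.2% of eligible (81.2% ending in reassurance)
  BMD-FRAX tests: 52.5% of eligible (74.0% ending in reassurance)
Screening performance on 10000 eligible individuals
  confusion: TP 3105, FP 16, FN 483, TN 6396
  sensitivity 86.5%, specificity 99.8%, PPV 99.5%, NPV 93.0%
  CRF-FRAX tests: 50.5% of eligible (77.3% ending in reassurance)
  BMD-FRAX tests: 32.0% of eligible (66.8% ending in reassurance)
CRF-FRAX tests: relative reduction 37%; BMD-FRAX tests: relative reduction 39%
  sensitivity -9.5, specificity +0.3, PPV +0.5 (percentage points)
```

Reading it: against the BMD-FRAX reference standard, the default gate
(gSOS > 0.5 for men, > 0 for women ⇒ reassure without testing) cuts
CRF-FRAX tests by 37% and BMD-FRAX tests by 39% relative to the base
strategy, raises specificity and PPV slightly, and gives up ~9 points of
sensitivity — the trade-off the gate is designed to expose. The methods
vignette (`vignettes/genomic-prescreening.Rmd`) documents the models, the
surrogate's parameters, and what the synthetic cohorts do and do not
emulate.

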