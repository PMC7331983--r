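---
title: "Genomic pre-screening for fracture risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic pre-screening for fracture risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Staged fracture-risk screening programs (NOGG-style) first compute a
clinical-risk-factor FRAX probability (CRF-FRAX) for everyone eligible, send
the intermediate-risk band for a bone-mineral-density measurement and a
BMD-based FRAX (BMD-FRAX), and recommend treatment when the resulting 10-year
probability of major osteoporotic fracture reaches an age-specific
intervention threshold. Most of the screening effort is spent on people who
end up reassured. Because heel-ultrasound speed of sound (SOS) is a heritable
correlate of BMD, a polygenic score for SOS ("gSOS") can identify individuals
whose skeletal genetics make a treatment-qualifying BMD unlikely; reassuring
them *before* any FRAX testing trades a bounded loss of sensitivity for a
large reduction in test burden. This package implements that whole analysis
as a reusable pipeline on synthetic cohorts: score training, screening
simulation, and the accounting of the trade-off.

## The polygenic score estimator

`prs_fit()` is the core estimator. On the training rows it computes a per-SNP
association scan (`run_gwas()`: OLS slope of phenotype on dosage with
covariates, equivalent to the per-SNP linear model via projection). For each
p-value threshold in a grid (default $5\times10^{-8}$ to $1$, six sets), the
SNPs passing the threshold enter a LASSO

$$\min_\beta \; \frac{1}{2n}\lVert y - X\beta\rVert_2^2 + \lambda\lVert\beta\rVert_1$$

fitted over a 50-point log-spaced penalty path from $\lambda_{\max}$ (the
smallest penalty with an all-zero solution) down to
$10^{-3}\lambda_{\max}$, with warm starts. Every (threshold, $\lambda$)
candidate is scored on the disjoint model-selection rows and the candidate
with the lowest RMSE wins; exact ties break toward the sparser candidate and
then the larger penalty, so exactly one score goes forward to the untouched
test rows. The phenotype is residualized against the covariates (fitted on
the training rows only) before the LASSO, keeping the penalized design
genotype-only; the alternative — unpenalized covariates inside the solver —
gives essentially the same score here because the synthetic covariates are
independent of genotype.

The solver is cyclic coordinate descent on the Gram ("covariance") form,
written in C++: the Gram matrix of the union SNP set is computed once per
fit and sub-indexed per threshold, and the gradient is updated only when a
coordinate moves. Convergence is declared when the largest absolute
coefficient change in a full sweep falls below $10^{-7}$ on the standardized
scale (at most $10^4$ sweeps; non-convergence is an error, not a warning).
The test suite checks the analytic soft-threshold solution on orthonormal
designs, Karush–Kuhn–Tucker residuals below $10^{-6}$ on random instances,
and agreement with glmnet as an independent implementation.

`traditional_prs()` is the comparator: greedy LD clumping
(`ld_clump()`, index SNPs by ascending p-value, removing neighbours with
dosage $r^2$ above 0.05, ties toward the smaller column index, correlations
computed on the training rows) followed by a weighted allele sum using the
marginal GWAS betas. Because marginal betas double-count LD-shared signal,
the jointly fitted score is expected to explain more test-set variance, and
does so in the recovery tests. Scores are standardized (`prs_standardize()`)
to mean 0, SD 1 on a reference set (training rows by default), so gate
thresholds are in population SD units.

## The fracture-probability surrogate

Real FRAX is proprietary, so screening logic here runs on a transparent
monotone stand-in with the same interface (percent probabilities, with and
without BMD). The hazard is Gompertz-like with a complementary-log-log link:

$$P = 100\,(1 - e^{-H}), \qquad
H = s_{\text{sex}} \exp\Big\{b\,( \text{age}-50) + \textstyle\sum_f \log RR_f\, x_f
 + \log RR_{\text{BMI}} (\text{BMI}-25) + \log RR_{\text{BMD}} (T_c - T)\Big\}$$

with the BMD term only in BMD-FRAX. Defaults: baseline 10-year hazard at 50
of 0.034 (women) and 0.023 (men); log-hazard slope 0.05/year; relative risks
1.8 (prior fracture), 1.6 (glucocorticoids), 1.5 (parental hip fracture),
1.4 (alcohol), 1.35 (secondary osteoporosis), 1.3 (rheumatoid arthritis),
1.25 (smoking); 0.97 per BMI unit above 25; 1.6 per T-score SD below
$T_c = -1$. These sit at the canonical epidemiological values for the
factor-level gradients of fracture risk; $T_c$ is the typical femoral-neck
T-score of the older screened population, which makes CRF-FRAX the
BMD-FRAX of a population-average skeleton. Competing mortality is not
modelled; the age slope absorbs it. Calibration is asserted only as
envelopes: mean CRF-FRAX of 3–8% in a mid-life mixed cohort and 12–25% in an
older all-female cohort. If a cohort table already carries `crf_frax` /
`bmd_frax` columns (e.g. true FRAX computed externally), they are used
verbatim and the surrogate is bypassed.

The age-specific intervention threshold IT(age) is the CRF-FRAX of a
same-age woman whose only risk factor is a prior fragility fracture — the
NOGG convention, since nearly all such women would be treated.

## The screening algorithms

Eligibility: age ≥ 50, at least one of the seven binary clinical risk
factors, and a femoral-neck T-score available. `nogg_screen()` then applies,
in order: (1) auto-treatment of women ≥ 50 with a prior fragility fracture,
with zero FRAX tests; (2) CRF-FRAX triage — treat at or above
1.2 × IT(age), reassure below the lower assessment threshold, BMD-FRAX for
the band between; (3) treat after BMD-FRAX iff it reaches IT(age).
`gsos_nogg_screen()` inserts the gate: individuals with gSOS strictly above
their sex's threshold (defaults 0.5 men, 0 women) are reassured with no
further testing. Design choices that the flow text of guidelines leaves
open, fixed here for determinism:

* the auto-treatment box precedes the gate (the reference standard also
  auto-assigns those women an intervention, so gating them out would
  guarantee false negatives); configurable off;
* all treat-side comparisons use ≥, so tie behaviour is defined even though
  ties have measure zero for continuous surrogates;
* the lower assessment threshold defaults to the CRF-FRAX of a same-age
  reference woman with no risk factors; a multiplier-of-IT rule is available
  (`lower_assessment_rule = "multiplier"`);
* with `gate_placement = "after_crf"` the gate applies only to the
  intermediate band, leaving CRF-FRAX counts untouched — the variant in
  which only BMD tests are saved.

The reference standard (`reference_standard()`) is BMD-FRAX ≥ IT(age) or
auto-treatment, evaluated for every eligible individual regardless of the
strategy's path; sensitivity and specificity of "correct treatment
assignment" compare each strategy's treat/reassure calls against it.
Individuals the gate excludes count as predicted reassure. Ineligible
individuals appear in traces as `not_screened` and enter no denominator.

`select_gsos_thresholds()` formalizes the threshold choice as constrained
minimization: per sex, among grid thresholds whose within-sex sensitivity
stays at or above `min_sensitivity` (default 90%), minimize the number of
BMD tests performed on ultimately reassured individuals; ties break toward
the larger (laxer) threshold and an unattainable constraint returns `+Inf`
(no gate). The underlying choice in practice is a visual trade-off; the
constraint form makes it reproducible and auditable by exhaustive grid
re-evaluation, which the tests do. Note the asymmetry the per-sex reports
expose: women tolerate strict gates because auto-treated women — a large
share of all reference positives — bypass the gate, while men lose
sensitivity quickly, so their selected threshold is high or absent. The
acceptance script therefore reports thresholds selected under a
bounded-loss constraint (each sex concedes at most 10 points of its own
no-gate sensitivity).

## The synthetic cohort generator

`simulate_genotypes()` draws hard-call dosages by thresholding two
block-autoregressive latent Gaussian haplotypes per individual
(AR(1) correlation `block_rho` within blocks of `block_size` SNPs), giving
Hardy–Weinberg marginals at the drawn allele frequency and positive LD
within blocks — cheap, controllable, and sufficient for clumping and LASSO
behaviour; it is not a coalescent simulation. `simulate_phenotypes()` builds
SOS as a scaled sum of a true polygenic score over `n_causal` random SNPs
(target variance share `h2_sos`, default 0.25) plus Gaussian noise, and a
BMD T-score as a location-shifted mixture correlated with SOS at
`sos_bmd_corr` (default 0.5, the middle of the reported SOS–BMD range)
after removing an age/sex trend (−0.02 T/year after 50, −0.3 in women, −0.5
baseline — there is no published generative model for this trend; these are
plausible round values and only relative placement matters downstream).
`simulate_risk_factors()` draws independent Bernoulli factors at
mid-life-biobank prevalences (`default_prevalences()`), with an optional
logistic age tilt; the joint dependence of risk factors is not modelled
beyond that tilt.

Two populations matter and they differ: score *training* emulates a mid-life
biobank (prior fracture ~10%), while *screening* evaluation emulates the
older validation cohorts such programs target, which have two to three
times the prior-fracture prevalence and a slight male excess among the
eligible. `simulate_screening_cohort()` therefore defaults to the pooled
validation-population rates (`validation_prevalences()`, prior fracture
20.3%, female fraction 0.46) and generates gSOS directly at a chosen
correlation with de-trended BMD (default 0.45) without genotypes — the
fast path for screening experiments. This matters scientifically: the
gate's headline property (large BMD-test reduction at modest sensitivity
cost) depends on auto-treated women being a substantial share of reference
positives, which is a property of the older, fracture-enriched screening
population, not of a mid-life biobank.

What passing tests therefore do and do not show: they validate the
machinery (estimator correctness, decision logic, accounting identities)
and the direction and rough magnitude of the burden/sensitivity trade-off
under the stated correlation structure; they do not reproduce
cohort-specific published magnitudes, which depend on restricted data,
real FRAX, real LD, and imputation quality. Dosage uncertainty, population
structure and admixture, X-chromosome SNPs, and missing genotypes are all
out of scope.

## Numerical and reproducibility choices

* Coordinate descent: tolerance $10^{-7}$ (standardized scale), max $10^4$
  sweeps, warm starts down each penalty path; Gram computed once per fit.
* GWAS p-values are floored at the smallest positive double so they stay in
  (0, 1]; monomorphic SNPs are flagged and reported as beta 0, p 1 rather
  than dropped silently.
* Clumping ties on equal p-values break toward the smaller column index.
* Model-selection ties: RMSE, then sparsity, then larger penalty.
* Splits: a uniform permutation cut at rounded cumulative fractions, so
  sizes match the requested 80% / 1.25% / 18.75% design within rounding.
* Every generator takes a seed and is bit-reproducible given it;
  `run_pipeline()` derives per-stage child seeds from one global seed so
  stages can be rerun in isolation.
* Problem sizes in the tests and the acceptance script (25,000 individuals
  × 2,000 SNPs with 200 causal for score recovery; 10,000 eligible for
  screening) are chosen so that sampling error is small relative to the
  asserted margins while a full run stays in the minutes range on one core.

## Known limitations

The surrogate's absolute probabilities are calibrated only to envelopes, so
absolute test burdens (e.g. the share of eligible needing BMD tests) differ
from published program figures even when relative reductions agree; the
independence of risk factors inflates the eligible fraction slightly; and
the single-parameterization surrogate stands in for country-specific FRAX
models. The LASSO solver targets dense Gram matrices up to a few thousand
SNPs — the intended scale here — not genome-wide sparse problems.
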