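---
title: "Methods: anthropometric screening indices and penalized selection in multi-country survey cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anthropometric screening indices and penalized selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package computes

`diabscreen` implements a per-country diabetes-screening analysis for
low- and middle-income-country (LMIC) survey cohorts. For each cohort it

1. derives the standard catalogue of anthropometric and biomarker indices
   from measured quantities (the `indices` functions),
2. applies an eligibility/imputation/rescaling/splitting/oversampling
   protocol with a strict fitted-on-train contract (`prepare_design()`),
3. selects diabetes predictors with an L1-penalized (lasso) logistic
   regression in which demographic covariates are controlled but never
   penalized (`fit_lasso_logistic()`, `cross_validate_lambda()`), and
4. reports confusion-matrix screening diagnostics on the untouched test
   partition (`classify()`, `confusion()`, `diagnostic_report()`).

Because the licensed survey extracts this analysis is designed for (SAGE,
STEPS, LASI, IFLS) cannot be redistributed, the package ships a synthetic
cohort generator (`generate_cohort()`, `default_country_suite()`) that
emulates their statistical structure. Everything downstream is exercised,
tested and benchmarked against those synthetic cohorts.

# The index catalogue

The registry (`default_registry()`) carries 54 predictor metrics: 26 core
(measured) metrics and 28 derived indices. BMI is classified as core —
although computable from weight and height it is inventoried with the
measured metrics in the survey extracts, and 26 + 28 = 54 only balances
under that convention. The exact core list is a reconstruction of the
usual SAGE/STEPS/LASI/IFLS instrument inventory (it includes separate
heart-rate and pulse-rate channels and a dried-blood-spot HbA1c); the
derived list is the formula catalogue documented on each
`compute_*()` function.

Unit policy: weights in kg, lengths/circumferences in cm (converted to
metres inside formulas), concentrations normalized to mg/dl on ingest
(glucose 18.016, cholesterol family 38.67, triglycerides 88.57 mg/dl per
mmol/l). LAP and VAI convert triglycerides (and, for VAI, HDL) back to
mmol/l internally, per their canonical definitions. TyG uses the natural
logarithm (cohort means ~8.2–8.8 are only consistent with ln);
AIP uses log10.

Several formulas circulate in more than one form. The defaults reproduce
the survey-table conventions this analysis targets, and each alternative is
available behind an explicit flag in `index_variants()`:

* `WHtR` defaults to WC(m)/H(m)^2 (table magnitudes ~0.35);
  `whtr_conventional` gives the textbook WC/H.
* `LDL.est` defaults to TC − (HDL + 0.38·TG); `friedewald_ldl` gives
  TC − HDL − TG/5.
* `RFM` defaults to the same-unit form 76/64 − 20·(H/WC);
  `rfm_as_printed` gives the mixed-unit H(m)/WC(cm) form found in some
  tabulations (magnitudes ~70).

ABSI, CI and HI use their canonical published forms
(ABSI = WC(m)/(BMI^{2/3}·H(m)^{1/2}); CI = WC(m)/(0.109·√(W/H(m)));
HI = HC·(W/W̄)^{−0.482}·(H/H̄)^{0.310}). The hip-index population
reference (W̄, H̄) defaults to cohort means and, inside
`prepare_design()`, is fitted on the training partition only — it is a
fitted parameter like any other.

Missing inputs propagate: an index is present exactly when all of its
required inputs are, and values that are computable but physiologically
odd (negative LAP or estimated LDL, BF% outside 0–100) are retained, never
silently dropped — the analysis protocol specifies no physiological
filtering.

# The synthetic cohort generator

Each respondent's measured quantities are generated from a latent-Gaussian
copula: five shared factors (skeletal frame, adiposity, blood pressure,
metabolic, grip) with fixed loadings, mapped through monotone marginal
transforms — truncated normal for anthropometry, moment-matched lognormal
for concentrations. This is the simplest structure that produces realistic
cross-index correlation (waist–weight ~0.7) without claiming to reproduce
any real survey's covariance, which is not publicly reported. Sex gaps in
height, weight and grip strength are planted mean-preservingly, with the
within-sex SD shrunk so pooled marginals still match their targets.

The outcome is assigned by a logistic model,
`diabetes ~ Bernoulli(plogis(b0 + Σ βj·zj))`, where `zj` are
**z-standardized** predictor values (measured or derived) computed on the
complete, pre-masking data, and `b0` is solved by bisection so the expected
prevalence matches the country target (tolerance 1e-4). The default truth —
fasting plasma glucose 1.5 and waist-to-height ratio 0.8 per SD on the
log-odds scale — encodes the premise that glycaemia and central adiposity
dominate, with the effect size a genuinely diagnostic biomarker carries
(OR ≈ 4.5 per SD of FPG). Per-SD scaling was chosen deliberately: scaling
the same coefficients by a min-max-normalized predictor instead makes the
planted signal statistically invisible at the study's sample sizes
(per-SD z-statistics near 1), which would make every recovery experiment
vacuous.

The 17 default country profiles are calibrated to the published
multi-country descriptives: sample sizes, diabetes prevalences computed
from printed yes/no counts (1.1%–27%), mean ages 35.8 (Uganda) to 62.8
(Mexico), mean BMIs 22.9–29.7, and three instrument archetypes for
predictor availability (STEPS-like lab panels; SAGE-like grip/pulse panels
without blood chemistry; a LASI-like anthropometry-heavy panel). Two
printed values were adjusted as evident typos: Uganda's FPG SD (printed
0.2 mg/dl, physiologically impossible for a cohort; set to 15) — Sudan's
large height SD (18.6 cm) is kept as printed since the truncation bounds
absorb it. Rates the source does not state were fixed once at realistic
survey levels: 2% of females pregnant, 2% underage, 0.5% of respondents
with no metrics at all, and 0.5% missing-completely-at-random within
available fields.

What the generator does **not** emulate: survey design effects (strata,
PSUs, weights), within-household correlation, measurement error and
digit preference, missingness that is informative rather than MCAR, and
any real survey's joint covariance. Tests passing on these cohorts
validate the pipeline's correctness and calibration, not substantive
epidemiological conclusions about real LMIC populations.

# Preprocessing protocol

The stage order is fixed: eligibility exclusions → index derivation →
stratified 80/20 split → covariate imputation (fit on train) → min-max
rescaling (fit on train) → minority oversampling (train only).

* **Exclusions** remove pregnant respondents, under-18s, and respondents
  with no available metric; the `exclusion_report` reconciles counts
  exactly. A pregnancy flag on a male record is treated as an inconsistent
  record (excluded, warned).
* **Imputation** is median/mode single imputation, covariates only (age,
  sex, race, caste) — predictor metrics are never imputed; respondents
  missing a retained predictor are dropped instead, mirroring the
  protocol's exclusion of respondents lacking metric information.
  Deterministic single imputation was chosen because only four covariates
  are in scope. A covariate a country never collected is dropped from the
  control set.
* **Rescaling** maps each predictor to [0, 1] with training-fitted
  minima/maxima; constant columns are dropped with a warning; test values
  outside the training range are *not* clipped. A `paper_faithful` flag
  restores whole-data fitting for fidelity to the source protocol's
  wording, at the cost of range leakage.
* **Splitting** is stratified by outcome with largest-remainder rounding,
  so a 1.1%-prevalence cohort retains cases in both partitions.
* **Oversampling** draws minority-class training rows with replacement to
  exact 1:1 parity. Interpolating oversamplers were deliberately excluded:
  they fabricate biomarker values.

# The penalized model

`fit_lasso_logistic()` minimizes

$$\frac{1}{n}\sum_i w_i\left[-y_i\eta_i + \log(1+e^{\eta_i})\right]
  + \lambda \sum_j p_j |\beta_j|$$

by iteratively reweighted least squares with cyclic coordinate-wise
soft-thresholding. Demographic controls get penalty factor $p_j = 0$ —
"controlling for" is implemented as never-penalized columns in the same
model, not pre-residualization. Features arrive min-max scaled and are not
re-standardized internally (double scaling would distort the penalty
geometry). Optional observation weights enter the likelihood
multiplicatively (record weights; default 1).

The inner solver alternates full sweeps (which certify the KKT conditions
over all coordinates) with covariance-updating sweeps over the active set,
so an active sweep costs O(|A|²) rather than O(|A|·n). Convergence is
declared when the largest absolute coefficient change in an outer
iteration falls below `tol` (default 1e-7); a fit that exhausts its
iteration budget is returned as-is with `converged = FALSE` and a warning.
IRLS variance weights are floored at 1e-9; for λ > 0 the penalty keeps
solutions finite even under separation. KKT certificates
(`kkt_check()`) and agreement with an independent convex solver to 1e-4
on small instances are part of the test suite.

**Numerical budgets.** Several index families are near-collinear by
construction (WHtR/WHT.5R/BRI are monotone transforms of nearly the same
ratio; weight/FFM/LBM correlate above 0.99). Coordinate descent on such
columns converges geometrically with ratio ≈ ρ², so driving the
max-coefficient change below 1e-7 at near-zero penalties costs arbitrarily
many sweeps for no change in any reported quantity. Pipeline runs
(`run_config()`) therefore use `cd_tol = 1e-3` with bounded sweep budgets —
coefficients are displayed at 0.1 precision and the selected sets are
unchanged against 1e-4 reruns — while single fits, oracle comparisons and
KKT tests run at 1e-7 to 1e-10.

**Penalty selection.** `cross_validate_lambda()` uses stratified 10-fold
CV over a warm-started path of 100 log-spaced penalties from λ_max down to
0.001·λ_max, scoring mean validation binomial deviance. Ties break toward
the larger (sparser) penalty. Because oversampling happens before model
fitting, fold assignment groups every oversampled copy with its source row
(`fold_groups`): plain fold assignment lets duplicated minority rows sit on
both sides of the train/validation boundary, which rewards overfitting and
drags the selected penalty to the bottom of the grid.

Two selection rules are available. The deviance-minimizing rule (`"min"`,
the pipeline default) is prediction-optimal but deliberately dense — it
keeps many small correlated coefficients. The one-standard-error rule
(`"1se"`) is the standard parsimonious answer to the *selection* question,
and is what the recovery experiment (`recovery_run()`) uses: under the
default truth, the 1se rule recovers both planted predictors in 20/20
seeds with well under one false selection per run among 20 nulls, whereas
the min rule recovers them with roughly 4–9 false selections — a
structural property of prediction-optimal CV, not a solver artifact.

One numerical subtlety: the CV path is solved at deviance precision, but
the fit that is *reported* is re-solved at the selected penalty to a tight
tolerance (warm-started from the path). Without that polish, coefficients
whose exact value is zero can survive as stale near-zeros from earlier
path steps and masquerade as selections.

# Diagnostics

Predictions are thresholded at 0.5 (the protocol states none; the
threshold is configurable) with the ≥ convention. False positive and false
negative rates are implemented as 1 − specificity and 1 − sensitivity —
the published diagnostic tables print complement pairs (e.g. TN 0.93 / FP
0.07), which fixes that interpretation. Rates whose class is absent are
reported as NA, never 0. Diagnostics are computed only on the raw,
never-oversampled test partition.

On the synthetic suite the held-out accuracies are genuinely moderate:
the planted truth is a two-predictor logistic signal, and for the
SAGE/LASI-archetype profiles the dominant predictor (FPG) is masked, so
their models see only its adiposity correlates. Published accuracies from
the licensed data (0.74–0.89) are not reproducible from synthetic cohorts
and are not a target of the test suite.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the formula oracle on 1000
random records, the solver oracle on 20 small instances, the recovery
experiment on 20 seeds of n = 5000 cohorts, and the 17-profile suite twice
at n = 2000 per country, comparing output digests for bit-identity. A
master seed determines every stochastic stage (generation, splitting,
oversampling, fold assignment) through derived sub-seeds; rerunning any
configuration reproduces its outputs exactly.

# Known limitations

* Survey-design variance (strata/PSU weights) is out of scope; record
  weights are accepted but default to 1.
* The copula's fixed loadings are a stylized correlation structure; no
  claim is made about any real survey's joint distribution.
* Selection inference is absent by design: nonzero lasso coefficients are
  reported descriptively, as in the analysis this package reproduces.
* Self-reported diabetes is the outcome; the generator plants no
  differential misreporting.
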