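# diabscreen

Screening-index derivation and penalized predictor selection for diabetes
in low- and middle-income-country (LMIC) survey cohorts.

Large household health surveys (WHO SAGE and STEPS, LASI, IFLS) measure a
handful of anthropometric quantities and biomarkers per respondent. Which
of the dozens of indices derivable from them — BMI and its relatives, waist
based central-adiposity indices (WHtR, ABSI, BRI, conicity index), body
composition estimates (BF%, FFM, LBM), lipid ratios (AIP, Castelli indices),
and glycaemic composites (TyG, LAP, VAI) — actually predict diagnosed
diabetes, and how does that differ by country? `diabscreen` implements the
full analysis pipeline for that question, for epidemiologists and
biostatisticians working with such extracts:

* **Indices.** A 54-metric registry (26 measured + 28 derived) with explicit
  unit handling, sex-specific branching, documented formula variants, and
  missing-input propagation (`default_registry()`, `derive_all()`).
* **Synthetic cohorts.** A latent-Gaussian-copula generator calibrated to
  the published descriptives of 17 LMIC surveys — per-country prevalence
  (1.1%–27%), marginal means/SDs, and instrument availability masks — with
  a configurable logistic outcome model (`default_country_suite()`,
  `generate_cohort()`). The licensed survey files themselves are out of
  scope; everything is testable without them.
* **Preprocessing.** Eligibility exclusions (pregnancy, age < 18, no
  metrics), train-fitted covariate imputation and min-max rescaling,
  stratified 80/20 splitting, and minority oversampling to 1:1 parity,
  in a fixed leakage-free order (`prepare_design()`).
* **Model.** Lasso-penalized logistic regression solved by IRLS with cyclic
  coordinate-wise soft-thresholding (compiled core), demographic controls
  kept unpenalized via penalty factors, and stratified cross-validated
  penalty selection with duplicate-aware folds (`fit_lasso_logistic()`,
  `cross_validate_lambda()`). The model minimizes

  ```
  (1/n) Σᵢ wᵢ [−yᵢηᵢ + log(1 + exp(ηᵢ))] + λ Σⱼ pⱼ |βⱼ|
  ```

  with `pⱼ = 0` for age/sex/race/caste columns and 1 for predictor metrics.
* **Diagnostics.** Confusion counts and accuracy / sensitivity /
  specificity / false-rate reporting on the untouched test partition
  (`diagnostic_report()`).

## Worked example

```r
library(diabscreen)

suite <- default_country_suite()          # 17 calibrated country profiles
cfg <- run_config(profile = suite[["Algeria"]], seed = 5, n = 2000)
res <- run_country(cfg)

res$exclusion_report
#> Eligibility exclusions
#>   initial records:      2000
#>   pregnant removed:     17
#>   aged < 18 removed:    48
#>   no metrics removed:   9
#>   eligible:             1926

subset(res$coefficients$predictors, selected, c(name, coefficient))
#>      name coefficient
#>       BPs   0.6043363
#>       FPG   9.3450246
#>       WHR   0.3821630
#>       WWI   0.5907818
#>      WHtR   1.1375166
#>       BRI   1.7733989

res$diagnostics
#> ACC 0.78 | TP 0.82 | TN 0.77 | FP 0.23 | FN 0.18
```

The selected set is the screening result: in this synthetic Algerian
cohort the cross-validated lasso keeps fasting plasma glucose (by far the
strongest coefficient) together with central-adiposity indices (waist-to-
height ratio, body roundness index, weight-adjusted waist index, waist-to-
hip ratio) and systolic blood pressure, and shrinks the other ~35
candidate metrics to exactly zero. Coefficients are on the min-max-scaled
scale, so 9.3 for FPG is the log-odds change across the observed FPG range
at the selected penalty; held-out sensitivity is 0.82 and specificity 0.77
at the 0.5 threshold.

The numbered drivers under `analysis/` run the whole study:

```sh
Rscript analysis/01_simulate.R     # simulate the 17-country suite, write cohorts + descriptives
Rscript analysis/02_fit.R          # per-country CV-lasso, wide coefficient table
Rscript analysis/03_diagnostics.R  # held-out screening performance table
```

Tables land in `results/` as CSV (one column per country, empty cells where
a country's instrument never measures a metric).

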