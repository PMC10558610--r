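# Parameter-recovery validation of the generator + selection stack.

#' Profile used for parameter-recovery experiments
#'
#' A generic survey profile with every measured field available and no
#' planted ineligible records, so the recovery experiment isolates the
#' selection behaviour of the cross-validated lasso.
#'
#' @param n cohort size.
#' @param prevalence outcome prevalence.
#' @return a [country_profile()].
#' @export
recovery_profile <- function(n = 5000, prevalence = 0.12) {
  country_profile("Recovery", n = n, prevalence = prevalence,
                  available_fields = measured_fields(),
                  pregnancy_rate = 0, underage_rate = 0, all_missing_rate = 0)
}

#' Null predictors used in the recovery experiment
#'
#' Twenty metrics carrying no effect in the default true model; they span
#' the anthropometric and biomarker families and include confounds correlated
#' with the true predictors (BMI with the waist-to-height ratio, total
#' cholesterol with glycaemia through the shared metabolic factor).
#'
#' @return character vector of 20 predictor names.
#' @export
recovery_null_predictors <- function() {
  c("Weight", "Height", "HC", "BMI", "BPs", "BPd", "HRate", "PRate",
    "GripS_L", "GripS_R", "ArmC", "UAL", "KH", "TC", "HDL", "Hb",
    "Potassium", "UC", "US", "BI")
}

#' Run one parameter-recovery replicate
#'
#' Generates a cohort from [recovery_profile()] under the default true model
#' (fasting glucose 1.5 and waist-to-height ratio 0.8 per SD on the logit
#' scale), assembles the 22-predictor design (the two true predictors plus
#' [recovery_null_predictors()]), min-max scales it, and selects predictors
#' by cross-validated lasso. Selection uses the one-standard-error rule by
#' default: recovery asks which predictors belong in the model, and the
#' parsimonious rule is the standard answer to that question — the
#' deviance-minimizing penalty is prediction-optimal and deliberately keeps
#' many small correlated coefficients.
#'
#' @param seed integer replicate seed.
#' @param n cohort size (default 5000).
#' @param n_folds CV folds.
#' @param rule penalty-selection rule (see [cross_validate_lambda()]).
#' @param tol,max_iter,max_inner coordinate-descent budgets.
#' @return list with `selected` (character), `hit` (both true predictors
#'   selected) and `n_false` (selected null predictors).
#' @export
recovery_run <- function(seed, n = 5000, n_folds = 10L, rule = "1se",
                         tol = 1e-3, max_iter = 15L, max_inner = 500L) {
  truth <- c("FPG", "WHtR")
  coh <- generate_cohort(recovery_profile(n = n),
                         generator_config(seed = seed,
                                          missing_at_random_rate = 0))
  pm <- predictor_matrix(coh$records)
  x <- rescale_minmax(as.matrix(pm[, c(truth, recovery_null_predictors())]))$scaled
  y <- coh$records$diabetes
  cv <- cross_validate_lambda(x, y, n_folds = n_folds, seed = seed + 1L,
                              rule = rule, tol = tol, max_iter = max_iter,
                              max_inner = max_inner)
  sel <- cv$fit$selected_predictors
  list(selected = sel, hit = all(truth %in% sel),
       n_false = length(setdiff(sel, truth)),
       lambda_selected = cv$lambda_selected)
}

#' Parameter-recovery experiment over many seeds
#'
#' @param seeds integer vector of replicate seeds.
#' @param ... passed to [recovery_run()].
#' @return data.frame with one row per seed (`seed`, `hit`, `n_false`).
#' @export
recovery_experiment <- function(seeds, ...) {
  rows <- lapply(seeds, function(s) {
    r <- recovery_run(s, ...)
    data.frame(seed = s, hit = r$hit, n_false = r$n_false)
  })
  do.call(rbind, rows)
}
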