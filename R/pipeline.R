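# Per-country end-to-end runs and the multi-country suite.

#' Run configuration for a single country
#'
#' @param profile a [country_profile()] (generator input), or NULL when
#'   `records` is supplied directly to [run_country()].
#' @param seed master seed; every stochastic stage derives its own sub-seed
#'   from it, so a configuration fully determines its outputs.
#' @param n cohort size override (NULL keeps the profile's).
#' @param train_fraction,n_folds,lambda_rule,threshold stage options.
#' @param paper_faithful fit min-max scaling on the pooled data.
#' @param availability_threshold predictor-missingness drop threshold.
#' @param nlambda,lambda_min_ratio penalty-grid controls.
#' @param true_coefficients,missing_at_random_rate generator options.
#' @param variants index formula variant flags.
#' @param cd_tol,cd_max_iter,cd_max_inner coordinate-descent budgets used for
#'   the pipeline's many warm-started fits. Near-collinear index columns
#'   (e.g. the waist-to-height family) make exact convergence at tiny
#'   penalties arbitrarily slow, so pipeline fits run at a 1e-3 coefficient
#'   tolerance (coefficients are displayed at 0.1 precision) with bounded
#'   sweeps; fits that hit the cap are returned as-is, flagged, and logged in
#'   the provenance block.
#' @return list of class `run_config`.
#' @export
run_config <- function(profile = NULL, seed = 1L, n = NULL,
                       train_fraction = 0.8, n_folds = 10L,
                       lambda_rule = "min", threshold = 0.5,
                       paper_faithful = FALSE, availability_threshold = 0.5,
                       nlambda = 100L, lambda_min_ratio = 0.001,
                       true_coefficients = c(FPG = 1.5, WHtR = 0.8),
                       missing_at_random_rate = 0.005,
                       variants = index_variants(),
                       cd_tol = 1e-3, cd_max_iter = 15L, cd_max_inner = 500L) {
  structure(list(profile = profile, seed = as.integer(seed), n = n,
                 train_fraction = train_fraction, n_folds = as.integer(n_folds),
                 lambda_rule = lambda_rule, threshold = threshold,
                 paper_faithful = paper_faithful,
                 availability_threshold = availability_threshold,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 true_coefficients = true_coefficients,
                 missing_at_random_rate = missing_at_random_rate,
                 variants = variants,
                 cd_tol = cd_tol, cd_max_iter = as.integer(cd_max_iter),
                 cd_max_inner = as.integer(cd_max_inner)),
            class = "run_config")
}

#' Run the full screening analysis for one country
#'
#' Executes the fixed stage order — generate (or take) records, eligibility
#' exclusions, index derivation, stratified split, covariate imputation,
#' min-max scaling, minority oversampling, cross-validated lasso, held-out
#' diagnostics — and collects the three report tables. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config a [run_config()].
#' @param records optional records data.frame; when NULL the cohort is
#'   generated from `config$profile`.
#' @param registry predictor registry.
#' @return object of class `country_result`: `country`, `exclusion_report`,
#'   `descriptives`, `coefficients` (predictor/control tables), `diagnostics`,
#'   `lambda_selected`, `cv_curve`, `design` provenance and warnings.
#' @export
run_country <- function(config, records = NULL, registry = default_registry()) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
                        invokeRestart("muffleWarning") }
  if (is.null(records)) {
    gc_ <- generator_config(seed = config$seed,
                            true_coefficients = config$true_coefficients,
                            missing_at_random_rate = config$missing_at_random_rate)
    cohort <- generate_cohort(config$profile, gc_,
                              n = if (is.null(config$n)) config$profile$n else config$n)
    records <- cohort$records
  }
  country <- if (!is.null(records$country)) records$country[1] else "cohort"

  design <- withCallingHandlers(
    prepare_design(records, registry,
                   train_fraction = config$train_fraction,
                   seed = config$seed,
                   paper_faithful = config$paper_faithful,
                   availability_threshold = config$availability_threshold,
                   variants = config$variants),
    warning = note)

  n_pre <- nrow(design$train_x) - length(design$oversample_map)
  groups <- c(seq_len(n_pre), design$oversample_map)
  cv <- withCallingHandlers(
    cross_validate_lambda(design$train_x, design$train_y,
                          penalty_factor = design$penalty_factor,
                          fold_groups = groups,
                          n_folds = min(config$n_folds,
                                        max(2L, min(table(design$train_y[seq_len(n_pre)])))),
                          seed = config$seed + 3L,
                          nlambda = config$nlambda,
                          lambda_min_ratio = config$lambda_min_ratio,
                          rule = config$lambda_rule,
                          tol = config$cd_tol,
                          max_iter = config$cd_max_iter,
                          max_inner = config$cd_max_inner),
    warning = note)

  prob <- predict_proba(cv$fit, design$test_x)
  diag <- diagnostic_report(confusion(classify(prob, config$threshold),
                                      design$test_y))
  structure(list(country = country,
                 prevalence = mean(records$diabetes, na.rm = TRUE),
                 exclusion_report = design$exclusion_report,
                 descriptives = descriptive_table(records),
                 coefficients = extract_report(cv$fit, registry),
                 diagnostics = diag,
                 lambda_selected = cv$lambda_selected,
                 cv_curve = cv$cv_curve,
                 fit = cv$fit,
                 provenance = c(design$provenance,
                                list(config_seed = config$seed,
                                     warnings = warnings_log))),
            class = "country_result")
}

#' Run the multi-country suite
#'
#' Runs [run_country()] for each profile (with per-country sub-seeds derived
#' from the master seed) and assembles wide report tables mirroring the
#' survey-publication layout: one column per country, NA where a predictor is
#' unavailable to that country's model.
#'
#' @param profiles named list of country profiles (default: the 17-profile
#'   suite); duplicate names are rejected.
#' @param seed master seed.
#' @param n per-country cohort size override (NULL keeps profile sizes).
#' @param ... further arguments passed to [run_config()].
#' @return object of class `suite_result`: `results` (per-country list),
#'   `coefficients` (wide data.frame), `diagnostics` (wide data.frame),
#'   `prevalence` (per-country empirical prevalence).
#' @export
run_suite <- function(profiles = default_country_suite(), seed = 1L, n = NULL, ...) {
  if (length(profiles) < 1) stop("need at least one profile")
  nms <- vapply(profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate country names in the suite")
  registry <- default_registry()
  results <- vector("list", length(profiles))
  names(results) <- nms
  for (i in seq_along(profiles)) {
    cfg <- run_config(profile = profiles[[i]], seed = seed + 101L * (i - 1L),
                      n = n, ...)
    results[[i]] <- run_country(cfg, registry = registry)
  }
  coef_wide <- data.frame(predictor = registry$name, stringsAsFactors = FALSE)
  for (nm in nms) {
    coef_wide[[nm]] <- results[[nm]]$coefficients$predictors$coefficient
  }
  diag_rows <- c("accuracy", "sensitivity", "specificity",
                 "false_positive_rate", "false_negative_rate")
  diag_wide <- data.frame(metric = c("ACC", "TP", "TN", "FP", "FN"),
                          stringsAsFactors = FALSE)
  for (nm in nms) {
    d <- results[[nm]]$diagnostics
    diag_wide[[nm]] <- unlist(d[diag_rows], use.names = FALSE)[c(1, 2, 3, 4, 5)]
  }
  prev <- vapply(results, function(r) r$prevalence, numeric(1))
  structure(list(results = results, coefficients = coef_wide,
                 diagnostics = diag_wide, prevalence = prev),
            class = "suite_result")
}

#' Descriptive table: counts/percentages and means/SDs
#'
#' Categorical variables (sex, race, caste, diabetes) are reported as
#' N (percentage); numeric variables (age and every available metric) as mean
#' and standard deviation (n - 1 denominator; a single observation reports an
#' undefined SD as NA).
#'
#' @param records records data.frame.
#' @return data.frame with columns `variable`, `level`, `n`, `pct`, `mean`,
#'   `sd`, `display`.
#' @export
descriptive_table <- function(records) {
  if (nrow(records) == 0) stop("no records")
  rows <- list()
  cat_vars <- intersect(c("sex", "race", "caste", "diabetes"), names(records))
  for (v in cat_vars) {
    x <- records[[v]]
    if (v == "diabetes") x <- ifelse(is.na(x), NA, ifelse(x == 1, "yes", "no"))
    x <- x[!is.na(x)]
    if (!length(x)) next
    tab <- table(x)
    for (lv in names(tab)) {
      n <- as.integer(tab[[lv]])
      pct <- 100 * n / length(x)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lv, n = n, pct = pct,
        mean = NA_real_, sd = NA_real_,
        display = sprintf("%d (%.1f%%)", n, pct), stringsAsFactors = FALSE)
    }
  }
  num_vars <- intersect(c("age", measured_fields()), names(records))
  for (v in num_vars) {
    x <- records[[v]][!is.na(records[[v]])]
    if (!length(x)) next
    mu <- mean(x)
    s <- if (length(x) > 1) stats::sd(x) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = NA_character_, n = length(x), pct = NA_real_,
      mean = mu, sd = s,
      display = if (is.na(s)) sprintf("%.3g (SD undefined)", mu)
                else sprintf("%.3g ± %.3g", mu, s),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deterministic digest of a result object
#'
#' Serializes the object (uncompressed, fixed serialization version) and
#' returns its MD5, so that two runs of the same configuration can be checked
#' for bit-identical outputs.
#'
#' @param x any R object.
#' @return MD5 hex string.
#' @export
result_digest <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE, version = 3)
  unname(tools::md5sum(f))
}

#' Write the suite report tables as delimited text
#'
#' @param suite a `suite_result`.
#' @param dir output directory (created if needed).
#' @return invisible vector of file paths.
#' @export
write_suite_tables <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(coefficients = file.path(dir, "coefficients.csv"),
             diagnostics = file.path(dir, "diagnostics.csv"),
             prevalence = file.path(dir, "prevalence.csv"))
  utils::write.csv(suite$coefficients, paths["coefficients"], row.names = FALSE, na = "")
  utils::write.csv(suite$diagnostics, paths["diagnostics"], row.names = FALSE, na = "")
  utils::write.csv(data.frame(country = names(suite$prevalence),
                              prevalence = unname(suite$prevalence)),
                   paths["prevalence"], row.names = FALSE)
  invisible(paths)
}

#' Prevalence percentages from printed survey counts
#'
#' Recomputes a prevalence percentage from integer yes/no counts, rounded to
#' the number of decimals at which the source table prints it.
#'
#' @param yes,no integer counts.
#' @param digits decimals to round to.
#' @return percentage.
#' @export
prevalence_from_counts <- function(yes, no, digits = 1) {
  stopifnot(yes >= 0, no >= 0, yes + no > 0)
  round(100 * yes / (yes + no), digits)
}

#' Published per-country diabetes yes/no counts
#'
#' The printed yes/no diabetes frequencies of the 17-country survey
#' descriptive table, shipped as a plain-text input for the printed-count
#' checks.
#'
#' @return data.frame with columns `country`, `yes`, `no`,
#'   `printed_yes_pct`, `printed_no_pct`.
#' @export
published_diabetes_counts <- function() {
  path <- system.file("extdata", "published_diabetes_counts.csv",
                      package = "diabscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
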