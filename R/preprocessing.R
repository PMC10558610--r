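# Eligibility, imputation, rescaling, splitting and oversampling.
#
# The stage order is fixed: exclusions -> derive -> split -> impute
# (fit on train) -> scale (fit on train) -> oversample (train only).
# prepare_design() is the enforced path; the stage functions carry guards
# against the most damaging out-of-order calls (double scaling, oversampling
# an unsplit table).

#' Apply eligibility exclusions
#'
#' Removes pregnant respondents, respondents aged under 18, and respondents
#' with no available predictor metric at all, in that order (each record is
#' counted once, under the first rule it trips). A pregnancy flag on a male
#' record is treated as an inconsistent record: it is excluded with the
#' pregnant group and a warning is raised.
#'
#' @param records records data.frame with `pregnant`, `age` and metric columns.
#' @return list with `records` (eligible rows) and `report`, an
#'   `exclusion_report` whose counts reconcile:
#'   `n_final = n_initial - n_pregnant_removed - n_underage_removed - n_no_index_removed`.
#' @export
apply_exclusions <- function(records) {
  n0 <- nrow(records)
  pregnant <- !is.na(records$pregnant) & records$pregnant
  if (any(pregnant & records$sex == "male", na.rm = TRUE)) {
    warning("pregnancy flag on male record(s); excluded as inconsistent")
  }
  keep1 <- records[!pregnant, , drop = FALSE]
  n_preg <- n0 - nrow(keep1)
  underage <- !is.na(keep1$age) & keep1$age < 18
  keep2 <- keep1[!underage, , drop = FALSE]
  n_under <- nrow(keep1) - nrow(keep2)
  metric_cols <- intersect(measured_fields(), names(keep2))
  has_metric <- if (length(metric_cols))
    rowSums(!is.na(keep2[, metric_cols, drop = FALSE])) > 0
  else rep(FALSE, nrow(keep2))
  keep3 <- keep2[has_metric, , drop = FALSE]
  n_noidx <- nrow(keep2) - nrow(keep3)
  report <- structure(list(n_initial = n0, n_pregnant_removed = n_preg,
                           n_underage_removed = n_under,
                           n_no_index_removed = n_noidx,
                           n_final = nrow(keep3)),
                      class = "exclusion_report")
  attr(keep3, "exclusions_applied") <- TRUE
  list(records = keep3, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Eligibility exclusions\n",
      "  initial records:      ", x$n_initial, "\n",
      "  pregnant removed:     ", x$n_pregnant_removed, "\n",
      "  aged < 18 removed:    ", x$n_underage_removed, "\n",
      "  no metrics removed:   ", x$n_no_index_removed, "\n",
      "  eligible:             ", x$n_final, "\n", sep = "")
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits by outcome class so that tiny-prevalence cohorts retain cases in
#' both partitions. Per-class training counts follow the largest-remainder
#' rule on `train_fraction * n_class`, so the total training size is
#' `round(train_fraction * n)` within one record of class-exact
#' stratification. Seed-deterministic.
#'
#' @param records records data.frame with a binary `diabetes` column.
#' @param train_fraction training share, default 0.8.
#' @param seed integer seed for the permutation.
#' @return list with `train`, `test`, and the row indices `train_idx`.
#' @export
split_train_test <- function(records, train_fraction = 0.8, seed) {
  y <- records$diabetes
  if (nrow(records) < 5) stop("need at least 5 records to split")
  if (length(unique(y[!is.na(y)])) < 2) stop("both outcome classes must be present")
  classes <- sort(unique(y))
  quota <- vapply(classes, function(cl) train_fraction * sum(y == cl), numeric(1))
  base <- floor(quota)
  n_train <- round(train_fraction * nrow(records))
  extra <- n_train - sum(base)
  if (extra > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      idx <- which(y == classes[k])
      sample(idx, min(base[k], length(idx)))
    }))
  })
  train_idx <- sort(train_idx)
  train <- records[train_idx, , drop = FALSE]
  test <- records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE]
  attr(train, "partition") <- "train"
  attr(test, "partition") <- "test"
  list(train = train, test = test, train_idx = train_idx)
}

#' Impute demographic covariates with training-set parameters
#'
#' Numeric covariates are filled with the training median, categorical ones
#' with the training mode; the same training-fitted values are applied to the
#' test partition. Predictor metrics are never imputed. A requested covariate
#' with no observed training value is rejected.
#'
#' @param train,test partitions from [split_train_test()].
#' @param covariates covariate column names (default age/sex/race/caste,
#'   restricted to columns present).
#' @return list with `train`, `test` and `params` (the fitted fill values).
#' @export
impute_covariates <- function(train, test = NULL,
                              covariates = intersect(demographic_fields(), names(train))) {
  params <- list()
  for (cv in covariates) {
    x <- train[[cv]]
    if (all(is.na(x))) stop("covariate '", cv, "' entirely missing in training data")
    if (is.numeric(x)) {
      params[[cv]] <- stats::median(x, na.rm = TRUE)
    } else {
      tab <- sort(table(x), decreasing = TRUE)
      params[[cv]] <- names(tab)[1]
    }
  }
  fill <- function(df) {
    for (cv in covariates) {
      miss <- is.na(df[[cv]])
      if (any(miss)) df[[cv]][miss] <- params[[cv]]
    }
    df
  }
  list(train = fill(train), test = if (!is.null(test)) fill(test), params = params)
}

#' Min-max rescaling fitted on training data
#'
#' `x' = (x - min)/(max - min)` with minima/maxima observed on the training
#' partition. Constant training columns are dropped with a warning (the
#' scaled value would be 0/0). Test values outside the training range are not
#' clipped, so mild extrapolation beyond [0, 1] is allowed. Applying the
#' transform to an already-scaled matrix is rejected, as is applying fitted
#' parameters to unseen feature names.
#'
#' @param features numeric matrix or data.frame.
#' @param params NULL to fit on `features` (training), or fitted params.
#' @return list with `scaled` (matrix) and `params` (per-feature min/max).
#' @export
rescale_minmax <- function(features, params = NULL) {
  x <- as.matrix(features)
  if (isTRUE(attr(features, "minmax_scaled")) || isTRUE(attr(x, "minmax_scaled"))) {
    stop("features are already min-max scaled; refusing to rescale")
  }
  if (is.null(params)) {
    mins <- apply(x, 2, min, na.rm = TRUE)
    maxs <- apply(x, 2, max, na.rm = TRUE)
    const <- maxs - mins <= 0
    if (any(const)) {
      warning("dropping constant feature column(s): ",
              paste(colnames(x)[const], collapse = ", "))
      x <- x[, !const, drop = FALSE]
      mins <- mins[!const]; maxs <- maxs[!const]
    }
    params <- list(min = mins, max = maxs)
  } else {
    unseen <- setdiff(colnames(x), names(params$min))
    if (length(unseen)) stop("fitted scaling has no parameters for: ",
                             paste(unseen, collapse = ", "))
    x <- x[, names(params$min)[names(params$min) %in% colnames(x)], drop = FALSE]
  }
  nm <- colnames(x)
  scaled <- sweep(sweep(x, 2, params$min[nm]), 2, params$max[nm] - params$min[nm], "/")
  attr(scaled, "minmax_scaled") <- TRUE
  list(scaled = scaled, params = params)
}

#' Oversample the minority class to 1:1 parity
#'
#' Random sampling with replacement of minority-class rows until class counts
#' are equal. All original rows are retained; every augmented row is an exact
#' copy of some original minority row. Applied to the training partition only
#' (the input must carry the `partition == "train"` mark set by
#' [split_train_test()], or `force = TRUE`).
#'
#' @param train training records with a binary `diabetes` column.
#' @param seed integer seed.
#' @param force skip the train-partition guard (used on derived matrices).
#' @return list with `records` (augmented) and `oversample_map`, the original
#'   row indices of the appended copies.
#' @export
oversample_minority <- function(train, seed, force = FALSE) {
  if (!force && !identical(attr(train, "partition"), "train")) {
    stop("oversampling is applied to the training partition only; ",
         "split the data first")
  }
  y <- train$diabetes
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("cannot oversample: a class is empty")
  deficit <- max(tab) - min(tab)
  if (deficit == 0) return(list(records = train, oversample_map = integer(0)))
  minority <- as.integer(names(tab)[which.min(tab)])
  if (minority != 1L) warning("minority class is the negative class")
  idx_min <- which(y == minority)
  extra <- with_seed(seed, sample(idx_min, deficit, replace = TRUE))
  out <- rbind(train, train[extra, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "partition") <- "train"
  attr(out, "oversampled") <- TRUE
  list(records = out, oversample_map = extra)
}

#' Build the full analysis design for one cohort
#'
#' Runs the fixed preprocessing protocol end to end: eligibility exclusions;
#' derivation of the 54-metric predictor matrix; stratified 80/20 split;
#' covariate imputation fitted on the training partition; dropping of
#' predictors unavailable or mostly missing in training
#' (`availability_threshold`); complete-case filtering on the retained
#' predictors; min-max scaling fitted on the training partition (or on the
#' pooled data when `paper_faithful`); one-hot encoding of categorical
#' controls (first level as reference); and minority oversampling of the
#' training rows. Demographic controls get penalty factor 0, predictor
#' metrics 1.
#'
#' @param records raw records data.frame.
#' @param registry predictor registry.
#' @param train_fraction training share.
#' @param seed integer; sub-seeds for split and oversampling derive from it.
#' @param paper_faithful fit the min-max scaling on all rows instead of the
#'   training partition (reproduces whole-data rescaling; leaks the test range).
#' @param availability_threshold drop predictors whose training missingness
#'   exceeds this proportion (default 0.5).
#' @param oversample logical; oversample the training minority class.
#' @param variants index formula variant flags.
#' @return object of class `analysis_design`: scaled train/test matrices
#'   (predictors then control columns), outcomes, penalty factors, fitted
#'   scaling/imputation parameters, oversample map, exclusion report and a
#'   provenance list of dropped columns/rows.
#' @export
prepare_design <- function(records, registry = default_registry(),
                           train_fraction = 0.8, seed = 1,
                           paper_faithful = FALSE,
                           availability_threshold = 0.5,
                           oversample = TRUE,
                           variants = index_variants()) {
  excl <- apply_exclusions(records)
  rec <- excl$records
  if (nrow(rec) < 5) stop("too few eligible records")

  sp <- split_train_test(rec, train_fraction, seed = seed + 1L)
  tr_idx <- sp$train_idx
  te_idx <- setdiff(seq_len(nrow(rec)), tr_idx)

  # the hip-index population reference is a fitted parameter too: training only
  ref <- if (all(is.na(rec$Weight[tr_idx])) || all(is.na(rec$Height[tr_idx]))) {
    list(mean_weight = 1, mean_height = 1)
  } else population_reference(rec[tr_idx, , drop = FALSE])
  pm <- predictor_matrix(rec, registry, ref = ref, variants = variants)

  covs <- intersect(demographic_fields(), names(rec))
  covs <- covs[vapply(covs, function(cv) !all(is.na(sp$train[[cv]])), logical(1))]
  imp <- impute_covariates(sp$train, sp$test, covariates = covs)

  # predictor availability resolved on the training partition
  miss_rate <- colMeans(is.na(pm[tr_idx, , drop = FALSE]))
  keep_pred <- names(miss_rate)[miss_rate <= availability_threshold]
  dropped_missing <- setdiff(colnames(pm), keep_pred)
  X <- pm[, keep_pred, drop = FALSE]
  cc_tr <- tr_idx[stats::complete.cases(X[tr_idx, , drop = FALSE])]
  cc_te <- te_idx[stats::complete.cases(X[te_idx, , drop = FALSE])]
  if (length(unique(rec$diabetes[cc_tr])) < 2) {
    stop("training partition lost an outcome class after complete-case filtering")
  }

  fit_rows <- if (paper_faithful) c(cc_tr, cc_te) else cc_tr
  sc <- rescale_minmax(X[fit_rows, , drop = FALSE])
  kept <- names(sc$params$min)
  tr_x <- rescale_minmax(X[cc_tr, kept, drop = FALSE], sc$params)$scaled
  te_x <- rescale_minmax(X[cc_te, kept, drop = FALSE], sc$params)$scaled
  dropped_constant <- setdiff(keep_pred, kept)

  enc <- encode_controls(imp$train[match(cc_tr, tr_idx), , drop = FALSE],
                         imp$test[match(cc_te, te_idx), , drop = FALSE],
                         covariates = covs)
  train_mat <- cbind(tr_x, enc$train)
  test_mat <- cbind(te_x, enc$test)
  pf <- c(rep(1, ncol(tr_x)), rep(0, ncol(enc$train)))
  names(pf) <- colnames(train_mat)
  y_tr <- rec$diabetes[cc_tr]
  y_te <- rec$diabetes[cc_te]

  os_map <- integer(0)
  if (oversample) {
    osdf <- data.frame(diabetes = y_tr)
    attr(osdf, "partition") <- "train"
    os <- oversample_minority(osdf, seed = seed + 2L)
    os_map <- os$oversample_map
    if (length(os_map)) {
      train_mat <- rbind(train_mat, train_mat[os_map, , drop = FALSE])
      y_tr <- c(y_tr, y_tr[os_map])
    }
  }
  attr(train_mat, "minmax_scaled") <- TRUE
  attr(test_mat, "minmax_scaled") <- TRUE

  structure(list(train_x = train_mat, train_y = y_tr,
                 test_x = test_mat, test_y = y_te,
                 penalty_factor = pf,
                 predictors = kept, controls = colnames(enc$train),
                 scaling = sc$params, imputation_params = imp$params,
                 oversample_map = os_map,
                 exclusion_report = excl$report,
                 provenance = list(
                   dropped_missing = dropped_missing,
                   dropped_constant = dropped_constant,
                   n_train_complete = length(cc_tr),
                   n_test_complete = length(cc_te),
                   covariates_used = covs,
                   paper_faithful = paper_faithful,
                   seed = seed)),
            class = "analysis_design")
}

# one-hot encoding of controls; age min-max scaled on train, categorical
# levels fixed on train with the first level as reference; unseen test levels
# map to the reference row (all zeros)
encode_controls <- function(train, test, covariates) {
  tr_cols <- list(); te_cols <- list()
  n_te <- if (is.null(test)) 0L else nrow(test)
  for (cv in covariates) {
    x <- train[[cv]]
    if (is.numeric(x)) {
      rng <- range(x)
      denom <- if (diff(rng) > 0) diff(rng) else 1
      tr_cols[[cv]] <- (x - rng[1]) / denom
      if (n_te) te_cols[[cv]] <- (test[[cv]] - rng[1]) / denom
    } else {
      levs <- sort(unique(x))
      for (lv in levs[-1]) {
        nm <- paste0(cv, "_", lv)
        tr_cols[[nm]] <- as.numeric(x == lv)
        if (n_te) te_cols[[nm]] <- as.numeric(test[[cv]] == lv)
      }
    }
  }
  tr <- if (length(tr_cols)) do.call(cbind, tr_cols) else matrix(0, nrow(train), 0)
  te <- if (n_te) {
    if (length(te_cols)) do.call(cbind, te_cols) else matrix(0, n_te, 0)
  } else NULL
  list(train = tr, test = te)
}
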