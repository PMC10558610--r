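# Lasso-penalized logistic regression with unpenalized demographic controls.

as_design_matrix <- function(x) {
  m <- if (is.matrix(x) && is.double(x)) x else {
    m2 <- as.matrix(x); storage.mode(m2) <- "double"; m2
  }
  if (anyNA(m)) stop("feature matrix contains missing values")
  m
}

# column ranges without the allocation overhead of apply()
matrixStats_range <- function(m) {
  p <- ncol(m)
  mins <- numeric(p); maxs <- numeric(p)
  for (j in seq_len(p)) {
    cj <- m[, j]
    mins[j] <- min(cj); maxs[j] <- max(cj)
  }
  rbind(mins, maxs)
}

#' Fit an L1-penalized logistic regression at a single penalty
#'
#' Minimizes `(1/n) * sum_i w_i * [-y_i*eta_i + log(1 + exp(eta_i))] +
#' lambda * sum_j pf_j * |beta_j|` by iteratively reweighted least squares
#' with cyclic coordinate-wise soft-thresholding. The intercept and any
#' column with penalty factor 0 (the demographic controls) are never
#' penalized. Convergence is declared when the largest coefficient change in
#' an outer iteration falls below `tol`; non-convergence returns the current
#' solution with `converged = FALSE`.
#'
#' @param x numeric feature matrix (already min-max scaled; no missing
#'   values; penalized columns must be non-constant).
#' @param y binary 0/1 outcome vector.
#' @param lambda non-negative penalty.
#' @param penalty_factor per-column multiplier on the penalty: 0 for
#'   unpenalized controls, 1 (default) for predictors.
#' @param weights optional observation weights (record weights), default 1.
#' @param intercept_init,beta_init warm start.
#' @param tol maximum absolute coefficient change at convergence.
#' @param max_iter maximum outer (IRLS) iterations.
#' @param max_inner maximum coordinate-descent sweeps per outer iteration.
#' @return object of class `lasso_fit`: `intercept`, named `coefficients`,
#'   `lambda`, `penalty_factor`, `converged`, `objective`,
#'   `selected_predictors` (penalized columns with nonzero coefficient).
#' @export
fit_lasso_logistic <- function(x, y, lambda, penalty_factor = rep(1, ncol(x)),
                               weights = rep(1, nrow(x)),
                               intercept_init = 0, beta_init = NULL,
                               tol = 1e-7, max_iter = 200L, max_inner = 100000L,
                               check_columns = TRUE) {
  m <- as_design_matrix(x)
  stopifnot(length(y) == nrow(m), all(y %in% c(0, 1)),
            length(penalty_factor) == ncol(m), all(penalty_factor >= 0),
            lambda >= 0, all(weights > 0))
  if (check_columns) {
    rng <- matrixStats_range(m)
    const <- rng[2, ] - rng[1, ] == 0
    if (any(const & penalty_factor > 0)) {
      stop("constant penalized feature column(s): ",
           paste(colnames(m)[const & penalty_factor > 0], collapse = ", "))
    }
  }
  if (is.null(beta_init)) beta_init <- rep(0, ncol(m))
  res <- .lasso_logistic_cd(m, as.numeric(y), as.numeric(weights),
                            as.numeric(penalty_factor), lambda,
                            intercept_init, as.numeric(beta_init),
                            tol, as.integer(max_iter), as.integer(max_inner))
  beta <- setNames(res$beta, colnames(m))
  obj <- .lasso_objective_cpp(m, as.numeric(y), as.numeric(weights),
                              as.numeric(penalty_factor),
                              if (is.finite(lambda)) lambda else 0,
                              res$intercept, res$beta)
  if (!res$converged) warning("lasso fit did not converge in ", max_iter,
                              " outer iterations (max delta ", signif(res$max_delta, 3), ")")
  structure(list(intercept = res$intercept, coefficients = beta,
                 lambda = lambda, penalty_factor = setNames(penalty_factor, colnames(m)),
                 converged = res$converged, objective = obj,
                 selected_predictors = names(beta)[penalty_factor > 0 & beta != 0],
                 n = nrow(m)),
            class = "lasso_fit")
}

#' Penalized objective value of a fit (or arbitrary coefficients)
#' @param fit a `lasso_fit`.
#' @param x,y,weights the data the objective is evaluated on.
#' @param lambda penalty (defaults to the fit's).
#' @param intercept,beta optional coefficients overriding the fit's.
#' @return scalar objective value.
#' @export
lasso_objective <- function(fit, x, y, weights = rep(1, nrow(x)),
                            lambda = fit$lambda, intercept = fit$intercept,
                            beta = fit$coefficients) {
  m <- as_design_matrix(x)
  .lasso_objective_cpp(m, as.numeric(y), as.numeric(weights),
                       as.numeric(fit$penalty_factor), lambda,
                       intercept, as.numeric(beta))
}

#' Smallest penalty with an all-zero penalized solution
#'
#' Fits the unpenalized part of the model only (intercept plus penalty-factor-0
#' controls) and returns the largest absolute penalized-coordinate gradient,
#' scaled by its penalty factor. For any `lambda >=` this value, every
#' penalized coefficient is exactly zero (KKT threshold). Without controls
#' this reduces to `max_j |<x_j, y - mean(y)>| / n`.
#'
#' @inheritParams fit_lasso_logistic
#' @return scalar `lambda_max`.
#' @export
lambda_max <- function(x, y, penalty_factor = rep(1, ncol(x)),
                       weights = rep(1, nrow(x))) {
  m <- as_design_matrix(x)
  base <- .lasso_logistic_cd(m, as.numeric(y), as.numeric(weights),
                             as.numeric(penalty_factor), Inf, 0,
                             rep(0, ncol(m)), 1e-10, 200L, 10000L)
  mu <- plogis(base$intercept + drop(m %*% base$beta))
  grad <- drop(crossprod(m, weights * (mu - y))) / sum(weights)
  pen <- penalty_factor > 0
  max(abs(grad[pen]) / penalty_factor[pen])
}

#' Karush-Kuhn-Tucker optimality certificate
#'
#' At an exact solution, every penalized coordinate j satisfies
#' `|grad_j| <= lambda * pf_j` when `beta_j = 0` and
#' `grad_j = -sign(beta_j) * lambda * pf_j` otherwise, where `grad_j` is the
#' unpenalized-loss gradient `(1/n) sum_i w_i x_ij (mu_i - y_i)`; unpenalized
#' coordinates (and the intercept) must have zero gradient.
#'
#' @param fit a `lasso_fit`.
#' @param x,y,weights the training data.
#' @param tol certificate tolerance.
#' @return list with `ok` (logical) and `max_violation`.
#' @export
kkt_check <- function(fit, x, y, weights = rep(1, nrow(x)), tol = 1e-6) {
  m <- as_design_matrix(x)
  mu <- plogis(fit$intercept + drop(m %*% fit$coefficients))
  W <- sum(weights)
  grad <- drop(crossprod(m, weights * (mu - y))) / W
  grad0 <- sum(weights * (mu - y)) / W
  pf <- fit$penalty_factor
  lam <- fit$lambda * pf
  viol <- abs(grad0)
  for (j in seq_along(grad)) {
    v <- if (pf[j] == 0) {
      abs(grad[j])
    } else if (fit$coefficients[j] == 0) {
      max(abs(grad[j]) - lam[j], 0)
    } else {
      abs(grad[j] + sign(fit$coefficients[j]) * lam[j])
    }
    viol <- max(viol, v)
  }
  list(ok = viol <= tol, max_violation = viol)
}

#' Warm-started solution path over a penalty grid
#'
#' @inheritParams fit_lasso_logistic
#' @param lambda decreasing penalty grid, or NULL for `nlambda` log-spaced
#'   values from [lambda_max()] down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio grid controls (glmnet-style defaults).
#' @return list with `lambda`, `intercepts`, `beta` (p x nlambda matrix) and
#'   `converged` per grid point.
#' @export
lasso_path <- function(x, y, lambda = NULL, nlambda = 100L,
                       lambda_min_ratio = 0.001,
                       penalty_factor = rep(1, ncol(x)),
                       weights = rep(1, nrow(x)), tol = 1e-7,
                       max_iter = 200L, max_inner = 100000L) {
  m <- as_design_matrix(x)
  if (is.null(lambda)) {
    lmax <- lambda_max(m, y, penalty_factor, weights)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  if (is.unsorted(rev(lambda))) stop("lambda grid must be decreasing")
  p <- ncol(m)
  betas <- matrix(0, p, length(lambda), dimnames = list(colnames(m), NULL))
  ints <- numeric(length(lambda))
  conv <- logical(length(lambda))
  b <- rep(0, p); b0 <- 0
  for (k in seq_along(lambda)) {
    fit <- suppressWarnings(
      fit_lasso_logistic(m, y, lambda[k], penalty_factor, weights,
                         intercept_init = b0, beta_init = b, tol = tol,
                         max_iter = max_iter, max_inner = max_inner,
                         check_columns = FALSE))
    b <- unname(fit$coefficients); b0 <- fit$intercept
    betas[, k] <- b; ints[k] <- b0; conv[k] <- fit$converged
  }
  list(lambda = lambda, intercepts = ints, beta = betas, converged = conv)
}

stratified_folds <- function(y, n_folds, seed, groups = NULL) {
  # groups: rows sharing a group id (oversampled copies of the same original
  # record) are assigned to the same fold, so copies never leak across the
  # train/validation boundary
  if (is.null(groups)) groups <- seq_along(y)
  folds <- integer(length(y))
  first <- !duplicated(groups)
  gfold <- integer(0)
  with_seed(seed, {
    yg <- y[first]
    ids <- groups[first]
    gf <- integer(length(ids))
    for (cl in unique(yg)) {
      idx <- sample(which(yg == cl))
      gf[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    gfold <- setNames(gf, ids)
  })
  folds <- unname(gfold[as.character(groups)])
  folds
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated penalty selection
#'
#' Stratified k-fold cross-validation over a warm-started penalty path. The
#' criterion is mean validation binomial deviance; `rule = "min"` selects the
#' minimizing penalty (ties broken toward the larger, sparser penalty),
#' `rule = "1se"` the largest penalty within one standard error of the
#' minimum. A fold whose training part loses an outcome class triggers a
#' refold with a shifted seed (logged as a warning); five failures reject.
#'
#' @inheritParams lasso_path
#' @param n_folds number of folds (default 10); must not exceed the minority
#'   class count.
#' @param seed fold-assignment seed.
#' @param rule `"min"` or `"1se"`.
#' @param fold_groups optional row-group ids: rows with the same id (e.g. an
#'   oversampled copy and its source record) are kept in the same fold, so
#'   duplicated minority rows never straddle the train/validation boundary.
#' @return list with `lambda_selected`, `cv_curve` (data.frame lambda /
#'   mean_deviance / se_deviance), `lambda`, `folds`, and `fit`, the final
#'   fit at the selected penalty on the full data.
#' @export
cross_validate_lambda <- function(x, y, penalty_factor = rep(1, ncol(x)),
                                  n_folds = 10L, seed = 1L,
                                  lambda = NULL, nlambda = 100L,
                                  lambda_min_ratio = 0.001,
                                  weights = rep(1, nrow(x)),
                                  rule = c("min", "1se"), tol = 1e-7,
                                  max_iter = 200L, max_inner = 100000L,
                                  fold_groups = NULL) {
  rule <- match.arg(rule)
  m <- as_design_matrix(x)
  if (n_folds < 2) stop("need at least 2 folds")
  if (min(table(y)) < n_folds) stop("n_folds exceeds the minority class count")
  if (is.null(lambda)) {
    lmax <- lambda_max(m, y, penalty_factor, weights)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  folds <- NULL
  for (try in 0:4) {
    cand <- stratified_folds(y, n_folds, seed + try, groups = fold_groups)
    ok <- all(vapply(seq_len(n_folds), function(k) {
      length(unique(y[cand != k])) == 2
    }, logical(1)))
    if (ok) { folds <- cand; break }
    warning("single-class CV training fold; refolding with shifted seed")
  }
  if (is.null(folds)) stop("could not build two-class CV folds")

  dev <- matrix(NA_real_, n_folds, length(lambda))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    path <- lasso_path(m[tr, , drop = FALSE], y[tr], lambda = lambda,
                       penalty_factor = penalty_factor,
                       weights = weights[tr], tol = tol,
                       max_iter = max_iter, max_inner = max_inner)
    eta <- sweep(m[!tr, , drop = FALSE] %*% path$beta, 2, path$intercepts, "+")
    pr <- plogis(eta)
    dev[k, ] <- vapply(seq_along(lambda),
                       function(l) binomial_deviance(y[!tr], pr[, l]), numeric(1))
  }
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2, sd) / sqrt(n_folds)
  i_min <- which(mean_dev <= min(mean_dev) + 1e-12)[1]  # grid decreasing: first = largest lambda
  i_sel <- if (rule == "1se") {
    which(mean_dev <= mean_dev[i_min] + se_dev[i_min])[1]
  } else i_min
  lambda_selected <- lambda[i_sel]
  # the path/CV fits only need deviance precision, but the model that gets
  # reported deserves a converged solve: warm-start from the path solution at
  # the selected penalty and polish at a tight tolerance, so no stale
  # near-zero coefficient survives into the selected set
  warm <- lasso_path(m, y, lambda = lambda[seq_len(i_sel)],
                     penalty_factor = penalty_factor, weights = weights,
                     tol = tol, max_iter = max_iter, max_inner = max_inner)
  fit <- suppressWarnings(
    fit_lasso_logistic(m, y, lambda_selected, penalty_factor, weights,
                       intercept_init = warm$intercepts[i_sel],
                       beta_init = warm$beta[, i_sel],
                       tol = min(tol, 1e-6),
                       max_iter = 1000L, max_inner = 100000L))
  list(lambda_selected = lambda_selected,
       cv_curve = data.frame(lambda = lambda, mean_deviance = mean_dev,
                             se_deviance = se_dev),
       lambda = lambda, folds = folds, fit = fit, rule = rule)
}

#' Predicted outcome probabilities
#'
#' `logistic(intercept + x %*% beta)`. The feature columns must match the
#' fit's coefficient names exactly (same set, any order).
#'
#' @param fit a `lasso_fit`.
#' @param newx feature matrix.
#' @return probability vector in (0, 1).
#' @export
predict_proba <- function(fit, newx) {
  m <- as_design_matrix(newx)
  if (is.null(colnames(m)) || !setequal(colnames(m), names(fit$coefficients)) ||
      ncol(m) != length(fit$coefficients)) {
    stop("feature columns do not match the fitted coefficients")
  }
  m <- m[, names(fit$coefficients), drop = FALSE]
  plogis(fit$intercept + drop(m %*% fit$coefficients))
}

#' Coefficient report in the survey-table style
#'
#' One row per registry predictor: the coefficient on the scaled scale
#' rounded to one decimal for display (zero-coefficient predictors shown as
#' 0.0), NA for predictors unavailable to the model. Controls are reported in
#' a separate block.
#'
#' @param fit a `lasso_fit`.
#' @param registry predictor registry used to enumerate rows.
#' @return list with `predictors` (data.frame name/coefficient/display/
#'   selected) and `controls` (data.frame name/coefficient).
#' @export
extract_report <- function(fit, registry = default_registry()) {
  pf <- fit$penalty_factor
  pred_names <- names(pf)[pf > 0]
  ctrl_names <- names(pf)[pf == 0]
  coefs <- setNames(rep(NA_real_, nrow(registry)), registry$name)
  coefs[intersect(pred_names, registry$name)] <-
    fit$coefficients[intersect(pred_names, registry$name)]
  predictors <- data.frame(
    name = registry$name,
    coefficient = unname(coefs),
    display = ifelse(is.na(coefs), NA_character_, sprintf("%.1f", coefs)),
    selected = !is.na(coefs) & coefs != 0,
    stringsAsFactors = FALSE)
  controls <- data.frame(name = ctrl_names,
                         coefficient = unname(fit$coefficients[ctrl_names]),
                         stringsAsFactors = FALSE)
  list(predictors = predictors, controls = controls)
}
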