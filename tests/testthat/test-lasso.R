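test_that("an all-penalized solution is zero at and above lambda_max", {
  prob <- small_logistic_problem(200, 5, seed = 61)
  lmax <- lambda_max(prob$x, prob$y)
  # the KKT threshold without controls equals max |<x_j, y - ybar>| / n
  direct <- max(abs(crossprod(prob$x, prob$y - mean(prob$y)))) / length(prob$y)
  expect_equal(lmax, direct, tolerance = 1e-6)
  f <- fit_lasso_logistic(prob$x, prob$y, lmax * (1 + 1e-8))
  expect_true(all(f$coefficients == 0))
  expect_identical(f$selected_predictors, character(0))
  f2 <- fit_lasso_logistic(prob$x, prob$y, lmax * 0.8)
  expect_gt(sum(f2$coefficients != 0), 0)
})

test_that("a zero-information design yields the intercept-only MLE", {
  with_seed_test(3, {
    y <- rbinom(300, 1, 0.25)
    x <- matrix(runif(300 * 3), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
    f <- fit_lasso_logistic(x, y, lambda = 50, tol = 1e-10)
    expect_equal(f$intercept, qlogis(mean(y)), tolerance = 1e-6)
    expect_true(all(f$coefficients == 0))
  })
})

test_that("coordinate descent matches the convex-solver oracle on 20 instances", {
  skip_if_not_installed("glmnet")
  with_seed_test(77, {
    worst <- 0
    for (i in 1:20) {
      n <- sample(30:60, 1); p <- sample(2:6, 1)
      prob <- small_logistic_problem(n, p, seed = 700 + i,
                                     beta = rnorm(p, 0, 1.2))
      lam <- runif(1, 0.01, 0.15)
      ours <- fit_lasso_logistic(prob$x, prob$y, lam, tol = 1e-10)
      oracle <- glmnet_oracle(prob$x, prob$y, lam)
      worst <- max(worst, max(abs(oracle - c(ours$intercept, ours$coefficients))))
      k <- kkt_check(ours, prob$x, prob$y)
      expect_true(k$ok)
    }
    expect_lt(worst, 1e-4)
  })
})

test_that("the frozen 30 x 4 reference problem reproduces the oracle solution", {
  prob <- small_logistic_problem(30, 4, seed = 424242, uniform_x = TRUE,
                                 beta = c(2.5, -2, 0, 0))
  f <- fit_lasso_logistic(prob$x, prob$y, 0.05, tol = 1e-10)
  # oracle coefficients computed once with an independent convex solver at
  # lambda = 0.05 and frozen here
  expect_equal(unname(c(f$intercept, f$coefficients)),
               c(0.3732415341, 0, -0.6439146992, 0, 0),
               tolerance = 1e-4)
})

test_that("unpenalized controls stay in the model at every lambda", {
  skip_if_not_installed("glmnet")
  prob <- small_logistic_problem(150, 5, seed = 88, beta = c(1.5, -1, 0.8, 0, 0))
  pf <- c(0, 1, 1, 1, 1)
  lmax <- lambda_max(prob$x, prob$y, pf)
  for (lam in c(lmax * 2, lmax, lmax / 4)) {
    f <- fit_lasso_logistic(prob$x, prob$y, lam, penalty_factor = pf, tol = 1e-10)
    expect_true(f$coefficients[1] != 0)  # control tracks its (nonzero) MLE
    k <- kkt_check(f, prob$x, prob$y)
    expect_true(k$ok)
  }
  # oracle agreement with mixed penalty factors
  f <- fit_lasso_logistic(prob$x, prob$y, 0.04, penalty_factor = pf, tol = 1e-10)
  oracle <- glmnet_oracle(prob$x, prob$y, 0.04, penalty_factor = pf)
  expect_lt(max(abs(oracle - c(f$intercept, f$coefficients))), 1e-4)
})

test_that("warm starts never worsen the penalized objective along the path", {
  prob <- small_logistic_problem(250, 6, seed = 55, beta = c(2, -1.5, 1, 0, 0, 0))
  path <- lasso_path(prob$x, prob$y, nlambda = 25, tol = 1e-9)
  for (k in 2:length(path$lambda)) {
    fit_k <- structure(list(intercept = path$intercepts[k],
                            coefficients = path$beta[, k],
                            penalty_factor = rep(1, 6),
                            lambda = path$lambda[k]), class = "lasso_fit")
    own <- lasso_objective(fit_k, prob$x, prob$y)
    warm <- lasso_objective(fit_k, prob$x, prob$y,
                            intercept = path$intercepts[k - 1],
                            beta = path$beta[, k - 1])
    expect_lte(own, warm + 1e-10)
  }
})

test_that("KKT certificates hold on random fits", {
  with_seed_test(6, {
    for (i in 1:10) {
      prob <- small_logistic_problem(120, 5, seed = 60 + i,
                                     beta = rnorm(5))
      lam <- runif(1, 0.005, 0.2)
      f <- fit_lasso_logistic(prob$x, prob$y, lam, tol = 1e-10)
      k <- kkt_check(f, prob$x, prob$y, tol = 1e-6)
      expect_true(k$ok)
      # explicit form: active gradients pinned at -sign(beta)*lambda
      m <- prob$x
      mu <- plogis(f$intercept + drop(m %*% f$coefficients))
      grad <- drop(crossprod(m, mu - prob$y)) / nrow(m)
      act <- f$coefficients != 0
      if (any(act)) {
        expect_lt(max(abs(grad[act] + sign(f$coefficients[act]) * lam)), 1e-6)
      }
      if (any(!act)) expect_lt(max(abs(grad[!act])) - lam, 1e-6)
    }
  })
})

test_that("cross-validation is seed-deterministic and honours the grid", {
  prob <- small_logistic_problem(300, 6, seed = 91, beta = c(2, -1.5, 0, 0, 0, 0))
  cv1 <- cross_validate_lambda(prob$x, prob$y, n_folds = 5, seed = 10,
                               nlambda = 30, tol = 1e-8)
  cv2 <- cross_validate_lambda(prob$x, prob$y, n_folds = 5, seed = 10,
                               nlambda = 30, tol = 1e-8)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda_selected, cv2$lambda_selected)
  expect_identical(cv1$cv_curve, cv2$cv_curve)
  # grid of one lambda: that lambda is selected
  one <- cross_validate_lambda(prob$x, prob$y, n_folds = 5, seed = 10,
                               lambda = 0.03, tol = 1e-8)
  expect_identical(one$lambda_selected, 0.03)
  # folds are stratified: every fold carries both classes
  for (k in 1:5) {
    expect_identical(sort(unique(prob$y[cv1$folds == k])), c(0L, 1L))
  }
})

test_that("fold groups keep duplicated rows on one side of the boundary", {
  prob <- small_logistic_problem(200, 4, seed = 14, beta = c(1.5, -1, 0, 0))
  dup <- sample(which(prob$y == 1), 40, replace = TRUE)
  x2 <- rbind(prob$x, prob$x[dup, ])
  y2 <- c(prob$y, prob$y[dup])
  groups <- c(seq_along(prob$y), dup)
  folds <- diabscreen:::stratified_folds(y2, 5, seed = 2, groups = groups)
  expect_true(all(folds[seq_along(prob$y)][dup] == folds[-seq_along(prob$y)]))
})

test_that("probability predictions are monotone and column-checked", {
  prob <- small_logistic_problem(150, 4, seed = 19, beta = c(2, -1, 0, 0))
  f <- fit_lasso_logistic(prob$x, prob$y, 0.01, tol = 1e-9)
  p0 <- predict_proba(f, prob$x)
  expect_true(all(p0 > 0 & p0 < 1))
  # all-zero row gives logistic(intercept)
  z <- matrix(0, 1, 4, dimnames = list(NULL, colnames(prob$x)))
  expect_equal(unname(predict_proba(f, z)), plogis(f$intercept))
  # increasing a positive-coefficient feature increases the probability
  j <- which(f$coefficients > 0)[1]
  up <- prob$x; up[, j] <- up[, j] + 0.5
  expect_true(all(predict_proba(f, up) >= p0))
  # shuffled column order is fine; mismatched names are rejected
  expect_equal(predict_proba(f, prob$x[, rev(colnames(prob$x))]), p0)
  bad <- prob$x; colnames(bad)[1] <- "zz"
  expect_error(predict_proba(f, bad), "match")
})

test_that("coefficient reports show 0.0 for unselected and NA for unavailable", {
  reg <- default_registry()
  prob <- small_logistic_problem(200, 3, seed = 33, beta = c(2, 0, 0))
  x <- prob$x
  colnames(x) <- c("FPG", "WHtR", "BMI")
  x <- cbind(x, age = runif(200))
  f <- fit_lasso_logistic(x, prob$y, 0.02, penalty_factor = c(1, 1, 1, 0),
                          tol = 1e-9)
  rep_ <- extract_report(f, reg)
  expect_identical(nrow(rep_$predictors), 54L)
  expect_identical(rep_$controls$name, "age")
  fpg <- rep_$predictors[rep_$predictors$name == "FPG", ]
  expect_true(fpg$selected)
  # a metric the model never saw is NA, a zeroed one prints 0.0
  expect_true(is.na(rep_$predictors$coefficient[rep_$predictors$name == "LAP"]))
  zeroed <- rep_$predictors[rep_$predictors$name %in% c("WHtR", "BMI"), ]
  expect_true(all(zeroed$display %in% c("0.0", "-0.0") | zeroed$selected))
})
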