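# Shared fixtures: a small fast test profile and record builders.

test_profile <- function(n = 800, prevalence = 0.15,
                         fields = c("Weight", "Height", "WC", "HC", "BPs",
                                    "BPd", "FPG", "TC", "HDL", "TG"),
                         ...) {
  country_profile("Testland", n = n, prevalence = prevalence,
                  available_fields = fields, ...)
}

complete_record <- function(sex = "male", age = 45) {
  data.frame(country = "Testland", age = age, sex = sex,
             race = "group_a", caste = NA_character_, pregnant = FALSE,
             Weight = 75, Height = 170, WC = 88, HC = 98, BPs = 124, BPd = 80,
             HRate = 74, PRate = 73, GripS_L = 30, GripS_R = 32, ArmC = 29,
             UAL = 33, KH = 48, FPG = 95, TC = 180, HDL = 45, LDL = 110,
             TG = 130, Hb = 13.5, HbA1c = 5.6, A1C.DBS = 5.8, CRP = 2,
             Potassium = 40, UC = 90, US = 130, diabetes = 0L,
             stringsAsFactors = FALSE)
}

# small synthetic logistic problem for solver tests
small_logistic_problem <- function(n, p, seed, beta = NULL, uniform_x = FALSE) {
  with_seed_test(seed, {
    x <- if (uniform_x) matrix(runif(n * p), n, p) else matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("v", seq_len(p))
    if (is.null(beta)) beta <- c(2, -1.5, rep(0, p - 2))
    y <- rbinom(n, 1, plogis(-0.3 + drop(x %*% beta)))
    list(x = x, y = y)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# glmnet as the independent convex-solver oracle; glmnet rescales penalty
# factors to sum to nvars, so the penalty is adjusted to match ours exactly
glmnet_oracle <- function(x, y, lambda, penalty_factor = rep(1, ncol(x))) {
  scale_adj <- sum(penalty_factor) / ncol(x)
  lam <- lambda * scale_adj
  fit <- glmnet::glmnet(x, y, family = "binomial",
                        lambda = c(lam * 10, lam * 3, lam),
                        penalty.factor = penalty_factor,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
  as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
}
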