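# Synthetic multi-country survey cohorts.
#
# Latent-Gaussian copula: each measured field loads on a small set of shared
# factors (skeletal frame, adiposity, blood pressure, metabolic, grip) and is
# mapped through a monotone marginal transform — truncated normal for
# anthropometry, moment-matched lognormal for concentrations. The diabetes
# outcome is Bernoulli(logistic(b0 + sum beta_j x_j)) over min-max-scaled
# predictors, with b0 solved by bisection so the expected prevalence matches
# the country profile.

with_seed <- function(seed, expr) {
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

# factor loadings (frame, adiposity, bp, metabolic, grip) and marginal
# transform metadata per measured field
field_model <- function() {
  L <- rbind(
    Weight    = c(0.40, 0.75, 0.00, 0.00, 0.00),
    Height    = c(0.85, 0.00, 0.00, 0.00, 0.00),
    WC        = c(0.12, 0.85, 0.00, 0.05, 0.00),
    HC        = c(0.18, 0.78, 0.00, 0.00, 0.00),
    BPs       = c(0.00, 0.30, 0.68, 0.00, 0.00),
    BPd       = c(0.00, 0.25, 0.68, 0.00, 0.00),
    HRate     = c(0.00, 0.10, 0.25, 0.10, 0.00),
    PRate     = c(0.00, 0.10, 0.25, 0.10, 0.00),
    GripS_L   = c(0.55, 0.05, 0.00, 0.00, 0.65),
    GripS_R   = c(0.55, 0.05, 0.00, 0.00, 0.65),
    ArmC      = c(0.20, 0.60, 0.00, 0.00, 0.00),
    UAL       = c(0.70, 0.00, 0.00, 0.00, 0.00),
    KH        = c(0.70, 0.00, 0.00, 0.00, 0.00),
    FPG       = c(0.00, 0.30, 0.05, 0.45, 0.00),
    TC        = c(0.00, 0.15, 0.00, 0.40, 0.00),
    HDL       = c(0.00, -0.25, 0.00, -0.40, 0.00),
    LDL       = c(0.00, 0.15, 0.00, 0.40, 0.00),
    TG        = c(0.00, 0.30, 0.00, 0.50, 0.00),
    Hb        = c(0.25, 0.00, 0.00, 0.05, 0.00),
    HbA1c     = c(0.00, 0.25, 0.00, 0.50, 0.00),
    A1C.DBS   = c(0.00, 0.25, 0.00, 0.50, 0.00),
    CRP       = c(0.00, 0.30, 0.00, 0.20, 0.00),
    Potassium = c(0.00, 0.00, 0.00, 0.10, 0.00),
    UC        = c(0.00, 0.05, 0.00, 0.10, 0.00),
    US        = c(0.00, 0.05, 0.00, 0.10, 0.00)
  )
  transform <- c(Weight = "truncnorm", Height = "truncnorm", WC = "truncnorm",
                 HC = "truncnorm", BPs = "truncnorm", BPd = "truncnorm",
                 HRate = "truncnorm", PRate = "truncnorm",
                 GripS_L = "truncnorm", GripS_R = "truncnorm",
                 ArmC = "truncnorm", UAL = "truncnorm", KH = "truncnorm",
                 FPG = "lognormal", TC = "lognormal", HDL = "lognormal",
                 LDL = "lognormal", TG = "lognormal", Hb = "lognormal",
                 HbA1c = "lognormal", A1C.DBS = "lognormal", CRP = "lognormal",
                 Potassium = "lognormal", UC = "lognormal", US = "lognormal")
  bounds <- list(Weight = c(30, 220), Height = c(130, 210), WC = c(40, 200),
                 HC = c(50, 200), BPs = c(70, 260), BPd = c(40, 160),
                 HRate = c(35, 180), PRate = c(35, 180),
                 GripS_L = c(2, 90), GripS_R = c(2, 90), ArmC = c(15, 60),
                 UAL = c(20, 50), KH = c(35, 65))
  # male-minus-female additive gap, applied mean-preservingly (truncnorm only)
  sex_gap <- c(Height = 11, Weight = 8, GripS_L = 7, GripS_R = 7)
  list(loadings = L, transform = transform, bounds = bounds, sex_gap = sex_gap)
}

default_marginals <- function() {
  list(Weight = c(65, 14), Height = c(160, 9.5), WC = c(84, 13), HC = c(95, 12),
       BPs = c(124, 17), BPd = c(79, 11), HRate = c(77, 12), PRate = c(76, 11),
       GripS_L = c(23, 8), GripS_R = c(25, 8), ArmC = c(29, 4.5),
       UAL = c(33, 3.3), KH = c(48, 3.2),
       FPG = c(95, 20), TC = c(150, 35), HDL = c(42, 11), LDL = c(130, 28),
       TG = c(110, 45), Hb = c(13.4, 1.9), HbA1c = c(5.7, 1.1),
       A1C.DBS = c(5.95, 1.1), CRP = c(2.1, 3), Potassium = c(40, 20),
       UC = c(91, 35), US = c(135, 70))
}

#' Construct a country profile for the cohort generator
#'
#' @param name country label.
#' @param n default respondent count.
#' @param prevalence target diabetes proportion in (0, 1).
#' @param available_fields measured fields observed in that country's survey
#'   instrument; everything else is masked to NA after generation.
#' @param marginals named list of `c(mean, sd)` targets per field, merged over
#'   realistic defaults.
#' @param female_share proportion of females.
#' @param age_mean,age_sd age distribution (years), truncated at 18 for the
#'   eligible population.
#' @param race_levels,race_probs,caste_levels,caste_probs categorical
#'   demographics; NULL means the survey did not collect the variable.
#' @param pregnancy_rate proportion of females flagged pregnant.
#' @param underage_rate proportion of respondents injected with age < 18.
#' @param all_missing_rate proportion of respondents with every metric missing.
#' @return object of class `country_profile`.
#' @export
country_profile <- function(name, n, prevalence, available_fields,
                            marginals = list(), female_share = 0.55,
                            age_mean = 40, age_sd = 13,
                            race_levels = NULL, race_probs = NULL,
                            caste_levels = NULL, caste_probs = NULL,
                            pregnancy_rate = 0.02, underage_rate = 0.02,
                            all_missing_rate = 0.005) {
  stopifnot(prevalence > 0, prevalence < 1, n >= 1)
  bad <- setdiff(available_fields, measured_fields())
  if (length(bad)) stop("unknown fields in profile: ", paste(bad, collapse = ", "))
  m <- default_marginals()
  for (nm in names(marginals)) m[[nm]] <- marginals[[nm]]
  structure(list(name = name, n = as.integer(n), prevalence = prevalence,
                 available_fields = available_fields, marginals = m,
                 female_share = female_share, age_mean = age_mean,
                 age_sd = age_sd, race_levels = race_levels,
                 race_probs = race_probs, caste_levels = caste_levels,
                 caste_probs = caste_probs, pregnancy_rate = pregnancy_rate,
                 underage_rate = underage_rate,
                 all_missing_rate = all_missing_rate),
            class = "country_profile")
}

#' Generator configuration
#'
#' @param seed integer; fully determines the generated cohort.
#' @param true_coefficients named numeric vector of logit-scale effects per
#'   standard deviation of the named predictor (measured fields or derived
#'   indices; predictors enter the outcome model z-standardized). The default
#'   — fasting glucose 1.5 and waist-to-height ratio 0.8 per SD, everything
#'   else zero — encodes the premise that glycaemia and central adiposity
#'   drive the outcome with the effect sizes a diagnostic biomarker carries.
#' @param intercept `"solve"` calibrates the intercept to the profile
#'   prevalence by bisection (tolerance 1e-4); `"fixed"` uses
#'   `intercept_value`.
#' @param intercept_value fixed intercept when `intercept = "fixed"`.
#' @param missing_at_random_rate per-field MCAR missingness within available
#'   fields.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             true_coefficients = c(FPG = 1.5, WHtR = 0.8),
                             intercept = c("solve", "fixed"),
                             intercept_value = NULL,
                             missing_at_random_rate = 0.005) {
  intercept <- match.arg(intercept)
  registry <- default_registry()
  bad <- setdiff(names(true_coefficients), registry$name)
  if (length(bad)) stop("true coefficients name unknown predictors: ",
                        paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), true_coefficients = true_coefficients,
                 intercept = intercept, intercept_value = intercept_value,
                 missing_at_random_rate = missing_at_random_rate),
            class = "generator_config")
}

# true-model predictors enter the outcome logit z-standardized: the declared
# effects are per-SD log-odds, so the default truth (FPG 1.5, WHtR 0.8) is a
# strong, identifiable signal rather than a near-null one
zscale <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

solve_intercept <- function(lp, target, tol = 1e-4) {
  f <- function(b0) mean(plogis(b0 + lp)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    stop("infeasible prevalence target ", target,
         " given the true-coefficient linear predictor")
  }
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol) return(mid)
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic survey cohort
#'
#' Draws `n` respondents from the latent-factor copula calibrated to the
#' profile's marginal targets, assigns demographics, plants pregnancy,
#' underage and all-metrics-missing records at the profile rates, assigns the
#' diabetes outcome from the configured logistic model (computed on the
#' complete, unmasked data), then masks fields outside the profile's
#' availability set and applies MCAR missingness. Byte-identical under a
#' fixed seed.
#'
#' @param profile a [country_profile()].
#' @param config a [generator_config()].
#' @param n respondent count; defaults to the profile's.
#' @return object of class `synthetic_cohort`: `records` (data.frame),
#'   `profile`, `config`, and `truth` (intercept, coefficients and the scaled
#'   true-predictor design actually used to assign outcomes).
#' @export
generate_cohort <- function(profile, config, n = profile$n) {
  stopifnot(inherits(profile, "country_profile"), inherits(config, "generator_config"))
  fm <- field_model()
  fields <- rownames(fm$loadings)
  with_seed(config$seed, {
    # demographics
    sex <- ifelse(runif(n) < profile$female_share, "female", "male")
    age <- as.integer(round(profile$age_mean + profile$age_sd *
                            qnorm_trunc(runif(n),
                                        (18 - profile$age_mean) / profile$age_sd,
                                        (100 - profile$age_mean) / profile$age_sd)))
    underage <- runif(n) < profile$underage_rate
    age[underage] <- sample(15:17, sum(underage), replace = TRUE)
    pregnant <- sex == "female" & runif(n) < profile$pregnancy_rate
    race <- if (!is.null(profile$race_levels))
      sample(profile$race_levels, n, replace = TRUE, prob = profile$race_probs)
    else rep(NA_character_, n)
    caste <- if (!is.null(profile$caste_levels))
      sample(profile$caste_levels, n, replace = TRUE, prob = profile$caste_probs)
    else rep(NA_character_, n)

    # latent factors -> fields
    K <- ncol(fm$loadings)
    Fmat <- matrix(rnorm(n * K), n, K)
    uniq <- sqrt(pmax(1 - rowSums(fm$loadings^2), 0.05))
    records <- data.frame(country = rep(profile$name, n), age = age, sex = sex,
                          race = race, caste = caste, pregnant = pregnant,
                          stringsAsFactors = FALSE)
    female <- sex == "female"
    fshare <- mean(female)
    for (f in fields) {
      z <- drop(Fmat %*% fm$loadings[f, ]) + uniq[f] * rnorm(n)
      tgt <- profile$marginals[[f]]
      gap <- fm$sex_gap[f]
      if (fm$transform[f] == "truncnorm") {
        sd_within <- tgt[2]
        shift <- rep(0, n)
        if (!is.na(gap)) {
          # split the male-female gap mean-preservingly and shrink the
          # within-sex sd so the pooled sd still matches the target
          shift <- ifelse(female, -gap * (1 - fshare), gap * fshare)
          sd_within <- sqrt(max(tgt[2]^2 - fshare * (1 - fshare) * gap^2,
                                (0.4 * tgt[2])^2))
        }
        x <- tgt[1] + shift + sd_within * z
        b <- fm$bounds[[f]]
        x <- pmin(pmax(x, b[1]), b[2])
      } else {
        s2 <- log(1 + (tgt[2] / tgt[1])^2)
        x <- exp(log(tgt[1]) - s2 / 2 + sqrt(s2) * z)
      }
      records[[f]] <- x
    }

    # outcome from the complete (pre-masking) data
    beta <- config$true_coefficients
    if (length(beta)) {
      pm <- predictor_matrix(records)
      xs <- vapply(names(beta), function(nm) zscale(pm[[nm]]), numeric(n))
      xs[is.na(xs)] <- 0
      lp <- drop(xs %*% beta)
    } else {
      xs <- matrix(numeric(0), n, 0)
      lp <- rep(0, n)
    }
    b0 <- if (config$intercept == "solve") solve_intercept(lp, profile$prevalence)
    else config$intercept_value
    diabetes <- as.integer(runif(n) < plogis(b0 + lp))
    records$diabetes <- diabetes

    # availability masking, planted all-missing records, MCAR
    masked <- setdiff(fields, profile$available_fields)
    for (f in masked) records[[f]] <- NA_real_
    all_missing <- runif(n) < profile$all_missing_rate
    records[all_missing, fields] <- NA_real_
    if (config$missing_at_random_rate > 0) {
      for (f in intersect(profile$available_fields, fields)) {
        hit <- runif(n) < config$missing_at_random_rate
        records[[f]][hit] <- NA_real_
      }
    }
    structure(list(records = records, profile = profile, config = config,
                   truth = list(intercept = b0, coefficients = beta,
                                scaled_design = xs)),
              class = "synthetic_cohort")
  })
}

# inverse-CDF truncated standard normal
qnorm_trunc <- function(u, a, b) {
  pa <- stats::pnorm(a); pb <- stats::pnorm(b)
  stats::qnorm(pa + u * (pb - pa))
}

#' The default 17-country profile suite
#'
#' Seventeen profiles calibrated to the published multi-country survey
#' descriptives: per-country sample sizes, diabetes prevalences computed from
#' printed yes/no counts (1.1%-27%), mean ages 35.8-62.8 years, mean BMIs
#' 22.9-29.7 (induced through the weight/height marginals), and three
#' instrument archetypes for predictor availability — STEPS-like panels with
#' glucose and (variably) lipids, SAGE-like panels with grip strength and
#' pulse but no blood chemistry, and a LASI-like anthropometry-heavy panel.
#'
#' @return named list of 17 [country_profile()] objects.
#' @export
default_country_suite <- function() {
  base_anthro <- c("Weight", "Height", "BPs", "BPd")
  steps <- function(extra) c(base_anthro, "WC", extra)
  sage <- c(base_anthro, "WC", "HC", "GripS_L", "GripS_R", "PRate")
  M <- function(...) list(...)
  profs <- list(
    country_profile("Afghanistan", 3721, 998 / 3721, female_share = 0.464,
      age_mean = 37.8, age_sd = 14.5,
      available_fields = steps(c("FPG", "TC", "UC", "US")),
      marginals = M(Weight = c(66.7, 15.2), Height = c(162, 9.5), WC = c(83.7, 17.5),
                    BPs = c(125, 15.2), BPd = c(81.1, 12), FPG = c(88.5, 22),
                    TC = c(147, 37.5), UC = c(91.1, 31.7), US = c(140, 75.5)),
      race_levels = c("pashtun", "tajik", "other"), race_probs = c(0.5, 0.3, 0.2)),
    country_profile("Algeria", 6815, 916 / 6815, female_share = 0.548,
      age_mean = 41.4, age_sd = 13.2,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL", "TG", "LDL")),
      marginals = M(Weight = c(73.1, 14.9), Height = c(166, 9.9), WC = c(89.8, 14.7),
                    HC = c(104, 12.9), BPs = c(126, 17.9), BPd = c(76.4, 10.7),
                    HRate = c(77.7, 11.4), FPG = c(95.6, 19.1), TC = c(150, 33.7),
                    HDL = c(45.8, 12.2), TG = c(105.4, 37.7), LDL = c(131, 28.4))),
    country_profile("Bahamas", 1643, 161 / 1643, female_share = 0.607,
      age_mean = 41.8, age_sd = 10.8,
      available_fields = steps("HRate"),
      marginals = M(Weight = c(73.8, 19.9), Height = c(167, 9.7), WC = c(74.9, 29.8),
                    BPs = c(128, 17), BPd = c(82.6, 11.8), HRate = c(79.7, 12.3))),
    country_profile("Bangladesh", 8046, 536 / 8046, female_share = 0.473,
      age_mean = 39.3, age_sd = 12.3,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL", "TG", "LDL", "UC", "US")),
      marginals = M(Weight = c(57.3, 11.3), Height = c(157, 9.1), WC = c(80.1, 11.2),
                    HC = c(91.6, 9.1), BPs = c(122, 17.7), BPd = c(80, 12.1),
                    HRate = c(77.5, 11.9), FPG = c(94.2, 17.1), TC = c(153, 38.9),
                    HDL = c(38.8, 9.8), TG = c(107, 61.8), LDL = c(163.1, 18.9),
                    UC = c(90.4, 73.7), US = c(124, 69.4))),
    country_profile("Ecuador", 4576, 291 / 4576, female_share = 0.575,
      age_mean = 41.1, age_sd = 14.3,
      available_fields = steps(c("HRate", "FPG", "TC")),
      marginals = M(Weight = c(68.6, 14.2), Height = c(158, 9.4), WC = c(90.2, 12),
                    BPs = c(121, 16.1), BPd = c(76.4, 10.7), HRate = c(75.5, 11.6),
                    FPG = c(90.5, 19.5), TC = c(153, 42.2)),
      race_levels = c("mestizo", "indigenous", "black", "mixed", "white", "other"),
      race_probs = c(0.842, 0.081, 0.034, 0.061, 0.026, 0.002) / 1.046),
    country_profile("Ethiopia", 8888, 97 / 8888, female_share = 0.577,
      age_mean = 36, age_sd = 12.8,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL", "TG", "LDL")),
      marginals = M(Weight = c(56.3, 10), Height = c(163, 9.1), WC = c(76.1, 10.2),
                    HC = c(89.9, 10.6), BPs = c(122, 17.5), BPd = c(79.2, 11.8),
                    HRate = c(78, 12.6), FPG = c(81.4, 17), TC = c(138, 33.8),
                    HDL = c(42.1, 13.4), TG = c(117, 10.3), LDL = c(125.1, 28.9))),
    country_profile("Jordan", 5527, 662 / 5527, female_share = 0.602,
      age_mean = 39.8, age_sd = 13.9,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL", "TG", "LDL", "UC", "US")),
      marginals = M(Weight = c(72, 17.7), Height = c(164, 9.7), WC = c(87.9, 16.2),
                    HC = c(105, 14.3), BPs = c(119, 17.3), BPd = c(79.6, 10.6),
                    HRate = c(78.1, 11), FPG = c(89, 26.8), TC = c(151.6, 19),
                    HDL = c(32.9, 5.2), TG = c(126, 15.7), LDL = c(141, 15),
                    UC = c(93.8, 52.5), US = c(150, 71.7))),
    country_profile("Lesotho", 2269, 62 / 2269, female_share = 0.659,
      age_mean = 43.1, age_sd = 12,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL")),
      marginals = M(Weight = c(66.7, 16.5), Height = c(160, 9.7), WC = c(85.3, 13.7),
                    HC = c(99.9, 15.4), BPs = c(131, 21), BPd = c(85.9, 13.4),
                    HRate = c(74.3, 12.4), FPG = c(83.9, 46.2), TC = c(104, 15.6),
                    HDL = c(28.4, 8.3))),
    country_profile("Liberia", 2389, 30 / 2389, female_share = 0.554,
      age_mean = 38.7, age_sd = 10.6,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "TG")),
      marginals = M(Weight = c(66.1, 15.9), Height = c(157, 13.5), WC = c(76.7, 20.8),
                    HC = c(91.1, 23.3), BPs = c(128, 20), BPd = c(80, 13.5),
                    HRate = c(79.7, 14.4), FPG = c(93.5, 17.1), TC = c(140, 38.8),
                    TG = c(99, 26.4))),
    country_profile("Marshall Islands", 2956, 362 / 2956, female_share = 0.519,
      age_mean = 39.8, age_sd = 13.9,
      available_fields = c(base_anthro, "ArmC", "FPG", "TC"),
      marginals = M(Weight = c(74.5, 18.7), Height = c(158, 10.1), WC = c(100, 15),
                    ArmC = c(30.3, 4.34), BPs = c(121, 18.7), BPd = c(75.3, 12.9),
                    FPG = c(103, 29.2), TC = c(156, 39.3))),
    country_profile("Sudan", 7295, 391 / 7295, female_share = 0.629,
      age_mean = 38.5, age_sd = 13.6,
      available_fields = steps(c("HRate", "FPG", "TC", "HDL", "Potassium", "UC", "US")),
      marginals = M(Weight = c(63.8, 15.7), Height = c(162, 18.6), WC = c(83.8, 15.9),
                    BPs = c(130, 18.1), BPd = c(84.9, 11), HRate = c(81, 12.6),
                    FPG = c(93.2, 13.6), TC = c(79.9, 20.2), HDL = c(22.8, 9.7),
                    Potassium = c(40.3, 25.5), UC = c(90.9, 11.6), US = c(121, 61.4))),
    country_profile("Uganda", 3781, 44 / 3781, female_share = 0.576,
      age_mean = 35.8, age_sd = 13.2,
      available_fields = steps(c("HC", "HRate", "FPG", "TC", "HDL", "UAL")),
      marginals = M(Weight = c(59.9, 12.5), Height = c(162, 9), WC = c(79.1, 9.82),
                    HC = c(93.4, 12), BPs = c(127, 17.6), BPd = c(82.7, 12),
                    HRate = c(74.5, 13.6), FPG = c(71, 15), TC = c(63.1, 17.4),
                    HDL = c(19.4, 9.7), UAL = c(33.6, 3.3))),
    country_profile("Indonesia", 35322, 778 / 35322, female_share = 0.518,
      age_mean = 40.5, age_sd = 15.5,
      available_fields = c(sage, "KH", "Hb", "HbA1c", "A1C.DBS", "CRP"),
      marginals = M(Weight = c(61.8, 15.1), Height = c(156, 8.5), WC = c(84.3, 11.9),
                    HC = c(92.6, 9.98), BPs = c(126, 15.8), BPd = c(79.1, 11.2),
                    PRate = c(76.9, 11.1), GripS_L = c(24.6, 7.3), GripS_R = c(25.9, 7.5),
                    KH = c(47.5, 3.18), Hb = c(13.4, 1.88), HbA1c = c(5.69, 1.14),
                    A1C.DBS = c(5.95, 1.1), CRP = c(2.03, 3.4))),
    country_profile("Ghana", 4735, 87 / 4735, female_share = 0.589,
      age_mean = 57.1, age_sd = 16.3,
      available_fields = sage,
      marginals = M(Weight = c(63.9, 15.4), Height = c(161, 11.2), WC = c(84.6, 15.8),
                    HC = c(92.4, 15.5), BPs = c(128, 21.6), BPd = c(78.2, 12.9),
                    PRate = c(77.1, 11.7), GripS_L = c(23.6, 10.7), GripS_R = c(25.7, 11.2))),
    country_profile("Mexico", 5908, 986 / 5908, female_share = 0.612,
      age_mean = 62.8, age_sd = 10.6,
      available_fields = sage,
      marginals = M(Weight = c(70.5, 13.8), Height = c(155, 9.5), WC = c(87.2, 12.1),
                    HC = c(98.4, 6.6), BPs = c(104, 11.8), BPd = c(74.2, 4.6),
                    PRate = c(75.6, 4.99), GripS_L = c(22, 8.4), GripS_R = c(23.3, 8.6))),
    country_profile("South Africa", 4223, 370 / 4223, female_share = 0.574,
      age_mean = 60.3, age_sd = 11.3,
      available_fields = sage,
      marginals = M(Weight = c(71.9, 17.2), Height = c(158, 12.6), WC = c(86.7, 17.1),
                    HC = c(96.5, 17.2), BPs = c(107, 13.7), BPd = c(75.1, 8.5),
                    PRate = c(77.8, 7.29), GripS_L = c(25.1, 5.6), GripS_R = c(27.7, 7)),
      race_levels = c("black", "mixed", "white", "asian", "other"),
      race_probs = c(0.638, 0.193, 0.077, 0.091, 0.001)),
    country_profile("India", 66856, 8060 / 66856, female_share = 0.578,
      age_mean = 57.8, age_sd = 11.6,
      available_fields = sage,
      marginals = M(Weight = c(62.9, 10.1), Height = c(155, 8.9), WC = c(85.4, 12.6),
                    HC = c(91.2, 9.9), BPs = c(128, 19), BPd = c(81.7, 10.3),
                    PRate = c(70.3, 11.4), GripS_L = c(20.3, 7.6), GripS_R = c(22.4, 8.1)),
      caste_levels = c("yes", "no"), caste_probs = c(0.963, 0.037))
  )
  names(profs) <- vapply(profs, `[[`, character(1), "name")
  profs
}

#' Write / read a cohort as delimited text
#'
#' Comma-delimited UTF-8 with a header row; missing values are empty cells
#' (never zeros). Doubles are written with 17 significant digits so that
#' write-then-read round-trips exactly.
#'
#' @param cohort a `synthetic_cohort` or a records data.frame.
#' @param path output file.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   records data.frame.
#' @export
write_cohort <- function(cohort, path) {
  records <- if (inherits(cohort, "synthetic_cohort")) cohort$records else cohort
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA_character_,
                          sprintf("%.17g", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if (!is.null(df$pregnant)) df$pregnant <- as.logical(df$pregnant)
  for (nm in intersect(c("country", "sex", "race", "caste"), names(df))) {
    df[[nm]] <- as.character(df[[nm]])
  }
  for (nm in intersect(measured_fields(), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}
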