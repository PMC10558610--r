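test_that("mass-ratio indices match hand-computed values", {
  q <- data.frame(Weight = c(70, 81, 100), Height = c(100, 180, 170),
                  WC = c(NA, NA, 100), HC = c(NA, NA, 110))
  out <- compute_mass_ratios(q)
  expect_equal(out$BMI, c(70, 25, 100 / 1.7^2))
  expect_equal(out$PI[2], 81 / 1.8^3, tolerance = 1e-12)
  expect_equal(out$WWI[3], 10)
  expect_equal(out$BI, c(0, 80, 70))
  # WHT.5R magnitude matches the survey-table scale (~6.9)
  q2 <- data.frame(Weight = 65, Height = 166, WC = 89.8, HC = 100)
  expect_equal(compute_mass_ratios(q2)$WHT.5R, 89.8 / sqrt(166), tolerance = 1e-12)
  expect_lt(abs(compute_mass_ratios(q2)$WHT.5R - 6.97), 0.01)
  # as-printed WHtR sits near 0.35; the conventional variant near 0.5
  expect_equal(compute_mass_ratios(q2)$WHtR, (89.8 / 100) / 1.66^2)
  conv <- compute_mass_ratios(q2, index_variants(whtr_conventional = TRUE))
  expect_equal(conv$WHtR, 89.8 / 166)
})

test_that("shape indices match hand-computed values and handle domains", {
  ref <- population_reference(mean_weight = 70, mean_height = 165)
  q <- data.frame(Weight = 70, Height = 165, WC = 80, HC = 90, sex = "female")
  out <- compute_shape_indices(q, ref = ref)
  expect_equal(out$AVI, (2 * 6400 + 0.7 * 100) / 1000)  # 12.87
  expect_equal(out$HI, 90)  # reference individual keeps their HC
  # BRI hand evaluation at WC 0.9 m, H 1.7 m
  q2 <- data.frame(Weight = 70, Height = 170, WC = 90, HC = 95, sex = "male")
  bri <- compute_shape_indices(q2, ref = ref)$BRI
  expect_equal(bri, 364.2 - 365.5 * sqrt(1 - (0.9 / (2 * pi))^2 / 0.85^2),
               tolerance = 1e-12)
  expect_lt(abs(bri - 3.93), 0.015)
  # female with H = WC in identical units sits exactly at RFM = 56
  q3 <- data.frame(Weight = 70, Height = 120, WC = 120, HC = 100, sex = "female")
  expect_equal(compute_shape_indices(q3, ref = ref)$RFM, 56)
  # BRI radicand < 0 (WC > pi * H) is unavailable, not NaN
  q4 <- data.frame(Weight = 200, Height = 60, WC = 190, HC = 100, sex = "male")
  expect_true(is.na(compute_shape_indices(q4, ref = ref)$BRI))
  expect_error(population_reference(mean_weight = -1, mean_height = 160),
               "positive")
})

test_that("composition and glycaemic indices match hand-computed values", {
  q <- data.frame(Weight = 81, Height = 180, age = 40, sex = "male",
                  TG = 100, FPG = 100, WC = 92, HDL = 50.5677, HC = 100)
  # BMI 25 male aged 40: BF% = 30 + 9.2 - 16.2 = 23
  expect_equal(compute_composition(q)$BFP, 23)
  q2 <- data.frame(Weight = 60, Height = 160, age = 30, sex = "female")
  expect_equal(compute_composition(q2)$LBM,
               0.29569 * 60 + 0.41813 * 160 - 43.2933)
  # FFM is weight scaled by (1 - BF%/100)
  comp <- compute_composition(q)
  expect_equal(comp$FFM, 81 * (1 - comp$BFP / 100))
  # TyG = ln 5000
  g <- compute_glycaemic_indices(q)
  expect_equal(g$TyG, log(5000))
  # female at WC = 58 has LAP 0 for any TG
  qf <- data.frame(Weight = 60, Height = 160, sex = "female", WC = 58,
                   TG = 250, FPG = 90, HDL = 50)
  expect_equal(compute_glycaemic_indices(qf)$LAP, 0)
  # VAI male reference: BMI 25, WC 92, TG 1.03 mmol/l, HDL 1.31 mmol/l
  qm <- data.frame(Weight = 81, Height = 180, sex = "male", WC = 92,
                   TG = 1.03 * 88.57, HDL = 1.31 * 38.67, FPG = 90)
  expect_equal(compute_glycaemic_indices(qm)$VAI, 92 / 86.68)
})

test_that("lipid indices match hand-computed values with both LDL variants", {
  q <- data.frame(TC = 200, HDL = 50, TG = 100)
  out <- compute_lipid_indices(q)
  expect_equal(out$LDL.est, 200 - (50 + 38))  # printed 0.38 coefficient
  expect_equal(out$CRI.I, 4)
  expect_equal(out$VLDL, 20)
  expect_equal(out$AIP, log10(2))
  expect_equal(out$CRI.II, 112 / 50)  # falls back to estimated LDL
  fried <- compute_lipid_indices(q, index_variants(friedewald_ldl = TRUE))
  expect_equal(fried$LDL.est, 200 - 50 - 20)
  # reference ratios
  q2 <- data.frame(TC = 100, HDL = 50, TG = 50)
  out2 <- compute_lipid_indices(q2)
  expect_equal(out2$AC, 1)
  expect_equal(out2$AIP, 0)
  # measured LDL takes precedence in CRI-II
  q3 <- data.frame(TC = 200, HDL = 50, TG = 100, LDL = 130)
  expect_equal(compute_lipid_indices(q3)$CRI.II, 2.6)
})

test_that("every formula matches the independent oracle to 1e-10 relative", {
  nms <- derived_index_names()
  with_seed_test(99, {
    worst <- 0
    for (i in seq_len(1000)) {
      inp <- random_oracle_input()
      rec <- data.frame(Weight = inp$W, Height = inp$H, WC = inp$WC,
                        HC = inp$HC, age = inp$age, sex = inp$sex,
                        TC = inp$TC, HDL = inp$HDL, TG = inp$TG,
                        FPG = inp$FPG, LDL = inp$LDL)
      ref <- population_reference(mean_weight = inp$Wbar, mean_height = inp$Hbar)
      got <- derive_all(rec, ref = ref)
      for (nm in nms) {
        want <- do.call(oracle_index, c(list(name = nm), inp))
        rel <- abs(got[[nm]] - want) / max(abs(want), 1e-12)
        worst <- max(worst, rel)
      }
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("ratio indices are invariant to joint unit rescaling", {
  with_seed_test(17, {
    for (i in 1:50) {
      inp <- random_oracle_input()
      k <- runif(1, 0.1, 10)
      base <- data.frame(Weight = inp$W, Height = inp$H, WC = inp$WC,
                         HC = inp$HC, TC = inp$TC, HDL = inp$HDL, TG = inp$TG)
      scaled_lipids <- transform(base, TC = TC * k, HDL = HDL * k, TG = TG * k)
      a <- compute_lipid_indices(base); b <- compute_lipid_indices(scaled_lipids)
      expect_equal(b$AC, a$AC, tolerance = 1e-12)
      expect_equal(b$CRI.I, a$CRI.I, tolerance = 1e-12)
      expect_equal(b$THR, a$THR, tolerance = 1e-12)
      expect_equal(b$AIP, a$AIP, tolerance = 1e-12)
      scaled_girth <- transform(base, WC = WC * k, HC = HC * k)
      expect_equal(compute_mass_ratios(scaled_girth)$WHR,
                   compute_mass_ratios(base)$WHR, tolerance = 1e-12)
    }
  })
})

test_that("sex branches differ by the exact documented offsets", {
  with_seed_test(23, {
    for (i in 1:20) {
      inp <- random_oracle_input()
      rec <- function(s) data.frame(Weight = inp$W, Height = inp$H, WC = inp$WC,
                                    HC = inp$HC, age = inp$age, sex = s)
      cf <- compute_composition(rec("female")); cm <- compute_composition(rec("male"))
      expect_equal(cf$BFP - cm$BFP, 10.8, tolerance = 1e-9)
      ref <- population_reference(mean_weight = 70, mean_height = 165)
      sf <- compute_shape_indices(rec("female"), ref = ref)
      sm <- compute_shape_indices(rec("male"), ref = ref)
      expect_equal(sf$RFM - sm$RFM, 12, tolerance = 1e-9)
    }
  })
})

test_that("key indices are monotone where the definitions demand it", {
  w <- seq(50, 120, by = 5)
  bmi <- compute_mass_ratios(data.frame(Weight = w, Height = 170))$BMI
  expect_true(all(diff(bmi) > 0))
  tg <- seq(50, 400, by = 25)
  tyg <- compute_glycaemic_indices(
    data.frame(Weight = 70, Height = 170, WC = 90, sex = "male",
               TG = tg, FPG = 100, HDL = 45))$TyG
  expect_true(all(diff(tyg) > 0))
  fpg <- seq(60, 250, by = 10)
  tyg2 <- compute_glycaemic_indices(
    data.frame(Weight = 70, Height = 170, WC = 90, sex = "male",
               TG = 100, FPG = fpg, HDL = 45))$TyG
  expect_true(all(diff(tyg2) > 0))
  wc <- seq(60, 120, by = 5)
  bri <- compute_shape_indices(
    data.frame(Weight = 70, Height = 170, WC = wc, HC = 95, sex = "male"),
    ref = population_reference(mean_weight = 70, mean_height = 170))$BRI
  expect_true(all(diff(bri) > 0))
})

test_that("unavailability propagates through the dependency graph", {
  reg <- default_registry()
  rec <- complete_record()
  # complete record: exactly 28 derived values present
  derived <- derive_all(rec, reg)
  derived_only <- derived[, setdiff(names(derived), "BMI")]
  expect_identical(ncol(derived_only), 28L)
  expect_true(all(!is.na(unlist(derived_only))))
  # all inputs missing: every derived value unavailable
  empty <- rec
  empty[intersect(measured_fields(), names(empty))] <- NA_real_
  expect_true(all(is.na(unlist(derive_all(empty, reg)))))
  # missing HC alone knocks out exactly the HC-dependent indices
  nohc <- rec; nohc$HC <- NA_real_
  d <- derive_all(nohc, reg)
  hc_dep <- c("AVI", "BAI", "WHR", "HI")
  expect_true(all(is.na(unlist(d[hc_dep]))))
  expect_true(all(!is.na(unlist(d[setdiff(names(d), hc_dep)]))))
  # missing TG knocks out every TG-dependent composite
  notg <- rec; notg$TG <- NA_real_
  d2 <- derive_all(notg, reg)
  tg_dep <- c("TyG", "LAP", "VAI", "THR", "AIP", "VLDL", "LDL.est")
  expect_true(all(is.na(unlist(d2[tg_dep]))))
  # measured LDL still present, so CRI.II survives a missing TG
  expect_false(is.na(d2$CRI.II))
})

test_that("registry inventory and serialization round-trip", {
  reg <- default_registry()
  expect_identical(nrow(reg), 54L)
  expect_identical(sum(reg$category == "core"), 26L)
  expect_identical(sum(reg$category != "core"), 28L)
  expect_false(anyDuplicated(reg$name) > 0)
  path <- tempfile(fileext = ".yaml")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(back, reg)
  bad <- reg; bad$name[2] <- bad$name[1]
  expect_error(validate_registry(bad), "unique")
})
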