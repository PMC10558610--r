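make_records <- function(n = 10) {
  rec <- do.call(rbind, replicate(n, complete_record(), simplify = FALSE))
  rec$age <- rep(40L, n)
  rec
}

test_that("exclusions remove pregnant, underage and metric-free records with a reconciled report", {
  rec <- make_records(10)
  rec$sex <- c("female", rep("male", 5), rep("female", 4))
  rec$pregnant[1] <- TRUE
  rec$age[2:3] <- 17L
  rec[4, intersect(measured_fields(), names(rec))] <- NA_real_
  out <- apply_exclusions(rec)
  expect_identical(out$report$n_initial, 10L)
  expect_identical(out$report$n_pregnant_removed, 1L)
  expect_identical(out$report$n_underage_removed, 2L)
  expect_identical(out$report$n_no_index_removed, 1L)
  expect_identical(out$report$n_final, 6L)
  expect_identical(nrow(out$records), 6L)
  with(out$report, expect_identical(
    n_final, n_initial - n_pregnant_removed - n_underage_removed - n_no_index_removed))
  # all eligible: identity
  ok <- make_records(5)
  out2 <- apply_exclusions(ok)
  expect_identical(out2$report$n_final, 5L)
  expect_identical(sum(out2$report$n_pregnant_removed,
                       out2$report$n_underage_removed,
                       out2$report$n_no_index_removed), 0L)
  # pregnant male is inconsistent: excluded, warned
  bad <- make_records(4)
  bad$sex <- "male"; bad$pregnant[2] <- TRUE
  expect_warning(out3 <- apply_exclusions(bad), "inconsistent")
  expect_identical(out3$report$n_pregnant_removed, 1L)
})

test_that("exclusion counts are conserved on random cohorts", {
  with_seed_test(5, {
    for (i in 1:10) {
      prof <- test_profile(n = 300, pregnancy_rate = runif(1, 0, 0.1),
                           underage_rate = runif(1, 0, 0.1),
                           all_missing_rate = runif(1, 0, 0.05))
      coh <- generate_cohort(prof, generator_config(seed = 100 + i))
      out <- apply_exclusions(coh$records)
      with(out$report, {
        expect_identical(n_initial, 300L)
        expect_identical(n_final,
                         n_initial - n_pregnant_removed - n_underage_removed -
                           n_no_index_removed)
        expect_identical(n_final, nrow(out$records))
      })
      expect_true(all(out$records$age >= 18))
      expect_false(any(out$records$pregnant, na.rm = TRUE))
    }
  })
})

test_that("covariate imputation is fitted on train and applied to test", {
  train <- data.frame(age = c(20, 30, NA), sex = c("male", "male", "female"),
                      race = c("a", "b", NA), caste = c("x", "x", "y"))
  test <- data.frame(age = NA_real_, sex = NA_character_,
                     race = NA_character_, caste = NA_character_)
  out <- impute_covariates(train, test)
  expect_equal(out$train$age[3], 25)  # median of observed
  expect_identical(out$test$age, 25)
  expect_identical(out$test$sex, "male")   # train mode
  expect_identical(out$test$caste, "x")    # train mode, not test mode
  # no missing values: identity
  full <- data.frame(age = c(20, 30), sex = c("male", "female"),
                     race = c("a", "b"), caste = c("x", "y"))
  expect_identical(impute_covariates(full, NULL)$train, full)
  # entirely-missing covariate is rejected
  allna <- data.frame(age = c(NA_real_, NA_real_), sex = c("m", "f"),
                      race = c("a", "a"), caste = c("x", "x"))
  expect_error(impute_covariates(allna, NULL), "entirely missing")
})

test_that("min-max rescaling fits on train, drops constants, never clips", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 3))
  expect_warning(out <- rescale_minmax(x), "constant")
  expect_identical(colnames(out$scaled), c("a", "c"))
  expect_equal(out$scaled[, "a"], c(0, 0.5, 1))
  # fitted params applied to test data: values outside [0,1] retained
  test <- cbind(a = c(8), c = c(-1))
  sc <- rescale_minmax(test, out$params)
  expect_equal(unname(sc$scaled[1, "a"]), 1.5)
  expect_equal(unname(sc$scaled[1, "c"]), -1 / 3)
  # double scaling is rejected
  expect_error(rescale_minmax(out$scaled), "already")
  # unseen feature names are rejected
  expect_error(rescale_minmax(cbind(zz = 1:3), out$params), "no parameters")
})

test_that("the split is stratified, exhaustive, disjoint and seed-deterministic", {
  rec <- make_records(1000)
  rec$diabetes <- rep(c(1L, 0L), c(100, 900))
  sp <- split_train_test(rec, 0.8, seed = 21)
  expect_identical(nrow(sp$train), 800L)
  expect_identical(nrow(sp$test), 200L)
  expect_identical(sum(sp$train$diabetes), 80L)
  expect_identical(sum(sp$test$diabetes), 20L)
  expect_identical(sort(c(sp$train_idx, setdiff(seq_len(1000), sp$train_idx))),
                   seq_len(1000))
  sp2 <- split_train_test(rec, 0.8, seed = 21)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_test(rec, 0.8, seed = 22)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  # n = 5 with one case: largest-remainder puts the case in train
  tiny <- make_records(5)
  tiny$diabetes <- c(1L, 0L, 0L, 0L, 0L)
  spt <- split_train_test(tiny, 0.8, seed = 1)
  expect_identical(sum(spt$train$diabetes), 1L)
  expect_identical(nrow(spt$train), 4L)
  # single-class input is rejected
  one <- make_records(6); one$diabetes <- 0L
  expect_error(split_train_test(one, 0.8, seed = 1), "both outcome classes")
})

test_that("minority oversampling reaches exact 1:1 parity with exact copies", {
  rec <- make_records(1000)
  rec$diabetes <- rep(c(1L, 0L), c(100, 900))
  rec$Weight <- rnorm(1000, 70, 10)
  sp <- split_train_test(rec, 0.8, seed = 2)
  os <- oversample_minority(sp$train, seed = 3)
  tab <- table(os$records$diabetes)
  expect_identical(unname(tab[["1"]]), unname(tab[["0"]]))
  expect_identical(length(os$oversample_map), 640L)  # 720:80 -> +640 copies
  # originals all retained, augmented rows are field-for-field copies
  strip <- function(df) {
    attr(df, "partition") <- NULL; attr(df, "oversampled") <- NULL
    rownames(df) <- NULL
    df
  }
  expect_identical(strip(os$records[seq_len(nrow(sp$train)), , drop = FALSE]),
                   strip(sp$train))
  extra <- os$records[-seq_len(nrow(sp$train)), , drop = FALSE]
  src <- sp$train[os$oversample_map, , drop = FALSE]
  expect_identical(strip(extra), strip(src))
  expect_true(all(extra$diabetes == 1L))
  # already balanced: identity
  bal <- sp$train[c(which(sp$train$diabetes == 1), which(sp$train$diabetes == 0)[1:80]), ]
  attr(bal, "partition") <- "train"
  os2 <- oversample_minority(bal, seed = 4)
  expect_identical(nrow(os2$records), nrow(bal))
  # determinism
  os3 <- oversample_minority(sp$train, seed = 3)
  expect_identical(os3$oversample_map, os$oversample_map)
})

test_that("out-of-order preprocessing calls are rejected", {
  rec <- make_records(20)
  rec$diabetes <- rep(c(1L, 0L), 10)
  # oversampling before splitting
  expect_error(oversample_minority(rec, seed = 1), "training partition")
  # empty minority class
  sp <- split_train_test(rec, 0.8, seed = 1)
  tr <- sp$train; tr$diabetes <- 0L
  attr(tr, "partition") <- "train"
  expect_error(oversample_minority(tr, seed = 1), "empty")
})

test_that("prepare_design is leakage-free end to end", {
  prof <- test_profile(n = 900, prevalence = 0.2)
  coh <- generate_cohort(prof, generator_config(seed = 8))
  d <- prepare_design(coh$records, seed = 8)
  # scaled training predictors live in [0,1]
  pred_cols <- d$predictors
  expect_true(all(d$train_x[, pred_cols] >= 0 & d$train_x[, pred_cols] <= 1))
  # oversampled rows only in training; test partition untouched and raw-sized
  expect_identical(length(d$test_y), d$provenance$n_test_complete)
  expect_identical(nrow(d$train_x),
                   d$provenance$n_train_complete + length(d$oversample_map))
  # every feature column has nonzero training variance
  expect_true(all(apply(d$train_x, 2, function(col) length(unique(col))) > 1))
  # outcome is not among features
  expect_false("diabetes" %in% colnames(d$train_x))
  # scaling parameters ignore the test partition: perturbing test rows leaves
  # the fitted minima/maxima unchanged
  rec2 <- coh$records
  sp <- split_train_test(apply_exclusions(rec2)$records, 0.8, seed = 8 + 1L)
  test_rows_global <- setdiff(seq_len(nrow(apply_exclusions(rec2)$records)),
                              sp$train_idx)
  excl <- apply_exclusions(rec2)$records
  excl$Weight[test_rows_global] <- excl$Weight[test_rows_global] * 1.5
  d2 <- prepare_design(excl, seed = 8)
  expect_identical(d$scaling$min, d2$scaling$min)
  expect_identical(d$scaling$max, d2$scaling$max)
  # paper-faithful mode does leak the pooled range, by design
  d3 <- prepare_design(coh$records, seed = 8, paper_faithful = TRUE)
  expect_false(identical(d$scaling$max, d3$scaling$max))
})

test_that("mostly-missing predictors are dropped per the availability rule", {
  prof <- test_profile(n = 600)
  coh <- generate_cohort(prof, generator_config(seed = 9))
  d <- prepare_design(coh$records, seed = 9)
  # masked fields (e.g. grip strength) cannot be predictors
  expect_false("GripS_L" %in% d$predictors)
  expect_true("FPG" %in% d$predictors)
  expect_true(all(c("TyG", "WHtR") %in% d$predictors))
  expect_true("GripS_L" %in% d$provenance$dropped_missing)
})
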