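test_that("ratios divide neutrophil and platelet counts by lymphocytes", {
  v <- data.frame(patient_id = "A", day = 1L,
                  neutrophils = c(4000, 3000), lymphocytes = c(2000, 1000),
                  platelets = c(2e5, 1.5e5))
  r <- compute_ratios(v)
  expect_equal(r$nlr, c(2, 3))
  expect_equal(r$plr, c(100, 150))
  v$lymphocytes[2] <- 0
  expect_error(compute_ratios(v), "lymphocyte")
})

test_that("observation horizon follows outcome and follow-up cap", {
  w <- window_config()
  expect_equal(observation_horizon(
    list(recurrence = FALSE, followup_end_day = 2400), w), 1825L)
  expect_equal(observation_horizon(
    list(recurrence = FALSE, followup_end_day = 900), w), 900L)
  expect_equal(observation_horizon(
    list(recurrence = TRUE, recurrence_day = 430,
         followup_end_day = 460), w), 430L)
})

test_that("the worked recurrent example reproduces all six NLR features", {
  co <- toy_cohort(days = c(30, 200, 400), nlr = c(2, 4, 3),
                   recurrence = TRUE, recurrence_day = 430)
  f <- extract_features(co)$features
  expect_equal(nrow(f), 1)
  expect_equal(f$NLR_mean, 3)
  expect_equal(f$NLR_maxmin, 2)
  expect_equal(f$NLR_Tx, 2)
  expect_equal(f$NLR_R, 3)
  expect_equal(f$NLR_Rmean, 0)
  expect_equal(f$NLR_RTx, 1)
})

test_that("a constant ratio series yields zero spread and zero differences", {
  co <- toy_cohort(days = c(20, 100, 300), nlr = c(2.5, 2.5, 2.5),
                   recurrence = FALSE)
  f <- extract_features(co)$features
  expect_equal(f$NLR_maxmin, 0)
  expect_equal(f$NLR_Rmean, 0)
  expect_equal(f$NLR_RTx, 0)
})

test_that("difference identities and nonnegative spreads hold on random cohorts", {
  co <- generate_cohort(sim_config(n_patients = 250, seed = 31))
  f <- extract_features(co)$features
  expect_equal(f$NLR_Rmean, f$NLR_R - f$NLR_mean, tolerance = 1e-12)
  expect_equal(f$NLR_RTx, f$NLR_R - f$NLR_Tx, tolerance = 1e-12)
  expect_equal(f$PLR_Rmean, f$PLR_R - f$PLR_mean, tolerance = 1e-12)
  expect_equal(f$PLR_RTx, f$PLR_R - f$PLR_Tx, tolerance = 1e-12)
  expect_true(all(f$NLR_maxmin >= 0))
  expect_true(all(f$PLR_maxmin >= 0))
  expect_true(all(rowSums(f[, paste0("stage_", c("I", "II", "III", "IV"))]) == 1))
})

test_that("vectorized extraction equals the naive loop oracle", {
  co <- generate_cohort(sim_config(n_patients = 200, seed = 8))
  ext <- extract_features(co)
  f <- ext$features
  for (i in seq_len(nrow(co$cases))) {
    case <- co$cases[i, ]
    vis <- co$visits[co$visits$patient_id == case$patient_id, ]
    oracle <- naive_case_features(case, vis)
    if (!is.null(oracle$reason)) {
      expect_true(case$patient_id %in% ext$exclusions$case_id)
    } else {
      row <- f[f$case_id == case$patient_id, ]
      expect_equal(unlist(row[names(oracle$values)]), oracle$values,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("windows excluding every visit produce exclusion records, not defaults", {
  co <- toy_cohort(days = c(120, 200, 400), nlr = c(2, 4, 3),
                   recurrence = TRUE, recurrence_day = 430)
  ext <- extract_features(co)  # no visit in day 14..90
  expect_equal(nrow(ext$features), 0)
  expect_equal(ext$exclusions$reason, "NO_TX_WINDOW_VISIT")

  co2 <- toy_cohort(days = c(30, 80), nlr = c(2, 4),
                    recurrence = TRUE, recurrence_day = 430,
                    followup_end_day = 430)
  ext2 <- extract_features(co2)  # no visit in day 340..460
  expect_equal(ext2$exclusions$reason, "NO_R_WINDOW_VISIT")

  co3 <- toy_cohort(days = 30, nlr = 2, recurrence = FALSE)
  ext3 <- extract_features(co3)
  expect_equal(ext3$exclusions$reason, "TOO_FEW_VISITS")
})

test_that("standardization uses population sd from fit rows only", {
  f <- data.frame(case_id = c("a", "b", "c"), NLR_mean = c(1, 3, 7),
                  sex_male = c(0, 1, 1), label = c(TRUE, FALSE, TRUE))
  sc <- fit_scaler(f, fit_rows = 1:2)
  std <- apply_scaler(sc, f)
  expect_equal(std$NLR_mean[1:2], c(-1, 1))       # population sd of {1,3} is 1
  expect_equal(std$NLR_mean[3], (7 - 2) / 1)      # held-out row, stored params
  expect_equal(std$sex_male, f$sex_male)          # binaries untouched
  f$NLR_mean <- c(2, 2, 2)
  expect_warning(fit_scaler(f), "zero-variance")
})

test_that("stage is one-hot encoded with exactly one indicator set", {
  co <- toy_cohort(days = c(30, 200), nlr = c(2, 3), recurrence = FALSE,
                   stage = "III")
  f <- extract_features(co)$features
  expect_equal(unlist(f[, paste0("stage_", c("I", "II", "III", "IV"))]),
               c(stage_I = 0, stage_II = 0, stage_III = 1, stage_IV = 0))
})
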