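test_that("logistic regression separates a linearly separable toy set", {
  df <- toy_feature_frame(40, 2, seed = 2)
  df$label <- df$f1 > 0  # perfectly separable
  m <- fit_model(model_spec("LR"), df)
  p <- predict_proba(m, df)
  expect_equal(mean((p >= 0.5) == df$label), 1.0)
})

test_that("fits are deterministic given spec, seed and data", {
  df <- toy_feature_frame(120, 4, beta = c(1, 0.5, 0, 0), seed = 3)
  for (kind in c("LR", "RF", "GB", "DNN")) {
    m1 <- fit_model(model_spec(kind, seed = 11), df)
    m2 <- fit_model(model_spec(kind, seed = 11), df)
    expect_identical(predict_proba(m1, df), predict_proba(m2, df),
                     label = kind)
  }
})

test_that("degenerate training inputs are rejected", {
  df <- toy_feature_frame(30, 2, seed = 4)
  df$label <- TRUE
  expect_error(fit_model(model_spec("LR"), df), "single class")
  df2 <- toy_feature_frame(30, 2, seed = 4)
  df2$f1[3] <- NA
  expect_error(fit_model(model_spec("LR"), df2), "missing|non-finite")
})

test_that("probabilities are in range and schemas are enforced", {
  df <- toy_feature_frame(100, 3, beta = c(2, -1, 0), seed = 5)
  for (kind in c("LR", "RF", "GB", "DNN")) {
    m <- fit_model(model_spec(kind, seed = 1), df)
    p <- predict_proba(m, df)
    expect_true(all(p >= 0 & p <= 1), label = kind)
  }
  m <- fit_model(model_spec("LR"), df)
  bad <- df
  names(bad)[names(bad) == "f2"] <- "g2"
  expect_error(predict_proba(m, bad), "f2")
})

test_that("LR probability equals the logistic of the fitted linear score", {
  df <- toy_feature_frame(150, 3, beta = c(1, -0.5, 0.2), seed = 6)
  m <- fit_model(model_spec("LR"), df)
  co <- m$fitted$coefficients
  x1 <- unlist(df[7, c("f1", "f2", "f3")])
  by_hand <- plogis(co[1] + sum(co[-1] * x1))
  expect_equal(predict_proba(m, df[7, ])[1], unname(by_hand),
               tolerance = 1e-12)
})

test_that("an identically zero feature column cannot change predictions", {
  df <- toy_feature_frame(150, 3, beta = c(1.2, -0.8, 0), seed = 7)
  df0 <- df
  df0$zzz <- 0
  df0 <- df0[, c("case_id", "f1", "f2", "f3", "zzz", "label")]
  for (kind in c("LR", "DNN")) {
    m <- fit_model(model_spec(kind, seed = 9), df)
    m0 <- fit_model(model_spec(kind, seed = 9), df0)
    tol <- if (kind == "LR") 1e-12 else 1e-6
    expect_equal(predict_proba(m0, df0), predict_proba(m, df),
                 tolerance = tol, label = kind)
  }
})

test_that("a constant model predicts the same probability everywhere", {
  m <- manual_lr_model(c(0.3, 0, 0), c("f1", "f2"))
  df <- toy_feature_frame(20, 2, seed = 8)
  p <- predict_proba(m, df)
  expect_true(all(p == p[1]))
})

test_that("permuted labels give chance-level cross-validated ROC-AUC", {
  df <- toy_feature_frame(200, 5, beta = c(1.5, 0, 0, 0, 0), seed = 10)
  aucs <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    perm <- df
    perm$label <- sample(perm$label)
    rep <- cross_validate(model_spec("LR", seed = r), perm,
                          cv_spec(n_folds = 5, seed = r))
    rep$summary$mean[rep$summary$metric == "roc_auc"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("every model learns a strongly planted PLR signal", {
  co <- generate_cohort(sim_config(n_patients = 800, effect_plt = 2.0,
                                   seed = 314))
  ext <- extract_features(co)
  for (kind in c("LR", "RF", "GB", "DNN")) {
    rep <- cross_validate(model_spec(kind, seed = 1), ext$features,
                          cv_spec(n_folds = 10, seed = 1))
    expect_gt(rep$summary$mean[rep$summary$metric == "roc_auc"], 0.7,
              label = kind)
  }
})

test_that("model artifacts survive a save/load round trip", {
  df <- toy_feature_frame(120, 3, beta = c(1, -0.5, 0), seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  for (kind in c("LR", "RF", "GB", "DNN")) {
    m <- fit_model(model_spec(kind, seed = 2), df)
    save_model(m, path)
    m2 <- load_model(path)
    expect_equal(predict_proba(m2, df), predict_proba(m, df),
                 tolerance = 1e-12, label = kind)
  }
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something_else"), bad)
  expect_error(load_model(bad), "artifact")
})
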