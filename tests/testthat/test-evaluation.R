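test_that("roc_auc matches hand-counted concordance on printed examples", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "both classes")
})

test_that("roc_auc equals brute-force pairwise concordance on random vectors", {
  set.seed(42)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    scores <- sample(grid, n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))[sample(n)]
    expect_equal(roc_auc(scores, labels), brute_roc_auc(scores, labels))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  set.seed(7)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(3 * scores - 1.5))
  ours <- roc_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("roc_auc is rank-based and antisymmetric under label reversal", {
  set.seed(9)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, 0.3)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)         # monotone transform
  expect_equal(roc_auc(qlogis(plogis(scores)), labels), a, tolerance = 1e-9)
  expect_equal(roc_auc(scores, 1 - labels), 1 - a)      # reversal
})

test_that("pr_auc equals hand-computed average precision", {
  # ranked desc: labels 1,0,1,0 -> AP = 0.5*1 + 0.5*(2/3)
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(pr_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)  # perfect ranking
  # all scores tied: single threshold, precision = prevalence
  expect_equal(pr_auc(rep(0.5, 8), c(1, 1, 0, 0, 0, 0, 0, 0)), 0.25)
  expect_error(pr_auc(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("pr_auc approaches prevalence for uninformative scores", {
  set.seed(11)
  n <- 20000
  labels <- rbinom(n, 1, 0.3)
  scores <- runif(n)
  expect_lt(abs(pr_auc(scores, labels) - 0.3), 0.02)
})

test_that("threshold metrics recover the stated confusion counts", {
  perfect <- threshold_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  low <- threshold_metrics(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(unname(low["sensitivity"]), 0)
  expect_equal(unname(low["specificity"]), 1)

  # TP 3, FP 1, TN 5, FN 1
  scores <- c(rep(0.9, 3), 0.9, rep(0.1, 5), 0.1)
  labels <- c(rep(1, 3), 0, rep(0, 5), 1)
  m <- threshold_metrics(scores, labels)
  expect_equal(unname(m), c(0.8, 0.75, 0.75, 5 / 6))
})

test_that("stratified folds balance label counts to within one unit", {
  labels <- rbinom(203, 1, 0.27)
  fold <- make_folds(labels, n_folds = 10, seed = 5)
  pos_per_fold <- tapply(labels, fold, sum)
  n_per_fold <- tapply(labels, fold, length)
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_lte(diff(range(n_per_fold - pos_per_fold)), 1)
})

test_that("group-aware folds never separate a derived case from its parent", {
  co <- generate_cohort(sim_config(n_patients = 250, seed = 17))
  sp <- split_cohort(co)
  ext <- extract_features(sp)
  g <- provenance_groups(sp)
  rep <- cross_validate(model_spec("LR", seed = 2), ext$features,
                        cv_spec(n_folds = 10, seed = 2), groups = g)
  fold <- rep$fold_assignment
  ids <- ext$features$case_id
  prov <- sp$metadata$provenance
  both <- prov[prov$derived_id %in% ids & prov$parent_id %in% ids, ]
  expect_gt(nrow(both), 0)
  for (i in seq_len(nrow(both))) {
    expect_equal(fold[ids == both$derived_id[i]],
                 fold[ids == both$parent_id[i]])
  }
})

test_that("cross-validation reports are reproducible for a fixed seed", {
  co <- generate_cohort(sim_config(n_patients = 120, seed = 23))
  ext <- extract_features(co)
  r1 <- cross_validate(model_spec("RF", seed = 4), ext$features,
                       cv_spec(n_folds = 5, seed = 4))
  r2 <- cross_validate(model_spec("RF", seed = 4), ext$features,
                       cv_spec(n_folds = 5, seed = 4))
  expect_identical(r1$folds, r2$folds)
})

test_that("external validation fills the 2x2 training-by-validation matrix", {
  co_tr <- generate_cohort(sim_config(n_patients = 250, seed = 41))
  co_va <- generate_cohort(sim_config(n_patients = 150, seed = 42))
  sp_tr <- split_cohort(co_tr)
  sp_va <- split_cohort(co_va)
  feats <- function(x) extract_features(x)$features
  spec <- model_spec("LR", seed = 6)
  trained <- list(original = train_full(spec, feats(co_tr)),
                  split = train_full(spec, feats(sp_tr)))
  validation <- list(original = feats(co_va), split = feats(sp_va))
  ev <- external_validate(trained, validation)
  expect_equal(nrow(ev), 4)
  expect_setequal(
    paste(ev$training_variant, ev$validation_variant),
    c("original original", "original split",
      "split original", "split split"))
  expect_true(all(ev$roc_auc >= 0 & ev$roc_auc <= 1))

  # resubstitution sanity: validating on the training rows themselves is
  # optimistic, so it should not fall materially below the CV mean
  cvm <- cross_validate(spec, feats(co_tr), cv_spec(n_folds = 10, seed = 6))
  cv_roc <- cvm$summary$mean[cvm$summary$metric == "roc_auc"]
  ev_self <- external_validate(trained["original"],
                               list(original = feats(co_tr)))
  expect_gte(ev_self$roc_auc, cv_roc - 0.05)
})

test_that("validation on a zero-effect cohort is at chance", {
  co_tr <- generate_cohort(sim_config(n_patients = 300, seed = 51))
  co_null <- generate_cohort(sim_config(n_patients = 400, effect_neut = 1,
                                        effect_plt = 1, effect_lymph = 1,
                                        seed = 52))
  spec <- model_spec("LR", seed = 3)
  trained <- list(original = train_full(spec,
                                        extract_features(co_tr)$features))
  ev <- external_validate(trained,
                          list(null = extract_features(co_null)$features))
  expect_lt(abs(ev$roc_auc - 0.5), 0.1)
})
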