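# Stratified (optionally group-aware) k-fold cross-validation and the
# ranking metrics used throughout: ROC-AUC in the Mann-Whitney formulation
# (ties count half) and PR-AUC by the average-precision summation
# convention (step-wise interpolation; trapezoidal PR interpolation is
# deliberately not used, as it is optimistically biased).

#' Cross-validation settings
#'
#' @param n_folds number of folds (default 10).
#' @param group_aware keep cases sharing a provenance group (a derived
#'   split case and its parent) in the same fold (default `TRUE`).
#' @param threshold probability cutoff for the confusion-matrix metrics.
#' @param seed fold-assignment seed; per-fold model seeds derive from it.
#' @return a `cv_spec` list.
#' @export
cv_spec <- function(n_folds = 10, group_aware = TRUE, threshold = 0.5,
                    seed = 1L) {
  if (n_folds < 2) stop_config("n_folds", "must be at least 2")
  structure(list(n_folds = as.integer(n_folds),
                 group_aware = isTRUE(group_aware),
                 threshold = threshold, seed = as.integer(seed)),
            class = "cv_spec")
}

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half (Mann-Whitney U formulation).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (logical or 0/1); positives = recurrent.
#' @return value in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision summation: with cases ranked by decreasing score,
#' AP = sum over distinct thresholds of (recall step) x (precision there).
#'
#' @inheritParams roc_auc
#' @return value in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1)
  if (n1 == 0) stop("pr_auc requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate only at distinct-score boundaries (last index of each tie run)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' @inheritParams roc_auc
#' @param threshold cutoff; scores at or above it are called positive.
#' @return named vector: accuracy, precision, sensitivity, specificity.
#'   Precision is `NaN` when nothing is called positive.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  c(accuracy = (tp + tn) / length(y),
    precision = tp / (tp + fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

#' Stratified, optionally group-aware, fold assignment
#'
#' Groups (or singleton cases) are stratified by whether they contain a
#' positive, shuffled within stratum, and dealt round-robin, so fold label
#' counts differ by at most one unit per stratum.
#'
#' @param labels binary labels.
#' @param n_folds number of folds.
#' @param seed RNG seed for the shuffle.
#' @param groups optional group id per row; rows sharing a group id are
#'   always assigned to the same fold.
#' @return integer fold index (1..n_folds) per row.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1L, groups = NULL) {
  y <- as.numeric(labels)
  if (is.null(groups)) groups <- as.character(seq_along(y))
  groups <- as.character(groups)
  units <- unique(groups)
  unit_pos <- vapply(units, function(g) any(y[groups == g] == 1), logical(1))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  unit_fold <- setNames(integer(length(units)), units)
  for (stratum in c(TRUE, FALSE)) {
    members <- units[unit_pos == stratum]
    if (!length(members)) next
    members <- sample(members)
    unit_fold[members] <- rep_len(seq_len(n_folds), length(members))
  }
  unname(unit_fold[groups])
}

summarize_folds <- function(folds_df) {
  metrics <- setdiff(names(folds_df), "fold")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_df[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) sd(folds_df[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )
}

#' Cross-validate one classifier on a feature table
#'
#' Standardization is refit on each training fold and applied verbatim to
#' its held-out fold; metrics are computed on held-out rows only.  Folds
#' are stratified by label and, when `cv$group_aware`, provenance groups
#' (derived split cases and their parents) stay within one fold.  A fold
#' without positives gets `NA` PR-AUC with a warning and is dropped from
#' that metric's mean.
#'
#' @param spec a [model_spec()].
#' @param features raw (unstandardized) feature data frame from
#'   [extract_features()], with `case_id` and `label`.
#' @param cv a [cv_spec()].
#' @param groups optional named group map from [provenance_groups()]
#'   (indexed by `case_id`); ignored unless `cv$group_aware`.
#' @param columns feature columns to use (default: all).
#' @return an `nlr_eval_report`: list with `folds` (per-fold metric data
#'   frame), `summary` (mean and sd per metric), and metadata.
#' @export
cross_validate <- function(spec, features, cv = cv_spec(), groups = NULL,
                           columns = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_spec"))
  columns <- columns %||% setdiff(names(features), c("case_id", "label"))
  y <- as.numeric(features$label)
  g <- NULL
  if (cv$group_aware && !is.null(groups)) g <- groups[features$case_id]
  fold <- make_folds(y, cv$n_folds, seed = cv$seed, groups = g)

  model_index <- match(spec$kind, names(DEFAULT_HYPERPARAMS))
  rows <- vector("list", cv$n_folds)
  for (k in seq_len(cv$n_folds)) {
    tr <- fold != k
    te <- fold == k
    if (!any(te)) next
    scaler <- fit_scaler(features[, c("case_id", columns, "label")],
                         fit_rows = which(tr))
    train_std <- apply_scaler(scaler, features[tr, c("case_id", columns,
                                                     "label")])
    test_std <- apply_scaler(scaler, features[te, c("case_id", columns,
                                                    "label")])
    fold_spec <- spec
    fold_spec$seed <- derive_seed(spec$seed, model_index, k)
    model <- fit_model(fold_spec, train_std)
    p <- predict_proba(model, test_std)

    yte <- y[te]
    roc <- if (length(unique(yte)) == 2) roc_auc(p, yte) else NA_real_
    pr <- if (sum(yte) > 0) {
      pr_auc(p, yte)
    } else {
      warning(sprintf("fold %d has no positives; PR-AUC recorded as NA", k),
              call. = FALSE)
      NA_real_
    }
    thr <- threshold_metrics(p, yte, threshold = cv$threshold)
    rows[[k]] <- data.frame(fold = k, roc_auc = roc, pr_auc = pr,
                            t(thr), row.names = NULL)
  }
  folds_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(folds = folds_df,
                 summary = summarize_folds(folds_df),
                 model = spec$kind, n_folds = cv$n_folds,
                 threshold = cv$threshold, seed = cv$seed,
                 features = columns,
                 fold_assignment = fold),
            class = "nlr_eval_report")
}

#' @export
print.nlr_eval_report <- function(x, ...) {
  cat(sprintf("<nlr_eval_report> %s, %d-fold CV, %d features\n",
              x$model, x$n_folds, length(x$features)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Train on a full feature table, keeping the scaler for later validation
#'
#' @param spec a [model_spec()].
#' @param features raw feature data frame with `label`.
#' @param columns feature columns to use (default: all).
#' @return list with the fitted `model`, its `scaler`, and `columns`.
#' @export
train_full <- function(spec, features, columns = NULL) {
  columns <- columns %||% setdiff(names(features), c("case_id", "label"))
  scaler <- fit_scaler(features[, c("case_id", columns, "label")])
  std <- apply_scaler(scaler, features[, c("case_id", columns, "label")])
  list(model = fit_model(spec, std), scaler = scaler, columns = columns)
}

#' Validate trained models on held-out cohort variants
#'
#' Builds the (training variant) x (validation variant) performance
#' matrix: each model, trained on the original or the split-augmented
#' feature table, is applied to each validation variant using the
#' *training* run's stored standardization parameters and feature set.
#'
#' @param trained named list of [train_full()] results, one per training
#'   variant (e.g. `original`, `split`).
#' @param validation named list of raw validation feature data frames,
#'   one per validation variant.
#' @param threshold probability cutoff for the confusion-matrix metrics.
#' @return data frame with one row per training x validation cell.
#' @export
external_validate <- function(trained, validation, threshold = 0.5) {
  rows <- list()
  for (tv in names(trained)) {
    tr <- trained[[tv]]
    for (vv in names(validation)) {
      feats <- validation[[vv]]
      std <- apply_scaler(tr$scaler, feats[, c("case_id", tr$columns,
                                               "label")])
      p <- predict_proba(tr$model, std)
      yv <- as.numeric(feats$label)
      thr <- threshold_metrics(p, yv, threshold)
      rows[[length(rows) + 1]] <- data.frame(
        model = tr$model$spec$kind,
        training_variant = tv, validation_variant = vv,
        n = length(yv),
        roc_auc = if (length(unique(yv)) == 2) roc_auc(p, yv) else NA_real_,
        pr_auc = if (sum(yv) > 0) pr_auc(p, yv) else NA_real_,
        t(thr), row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
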