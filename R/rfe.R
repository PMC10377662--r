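# Sensitivity-based recursive feature elimination.
#
# A feature's importance is the dynamic range of the model's predicted
# probability when that feature alone is swept across its observed
# training range, with every other numeric feature held at its training
# mean and every binary feature at zero.  The feature with the smallest
# dynamic range is removed, the model refit, and the sweep repeated until
# one feature remains; the retained set is the one maximizing the mean of
# the cross-validated ROC-AUC and PR-AUC along the trace.
#
# One-hot stage indicators are swept level-by-level against the all-zero
# background but eliminated as a single "stage" feature (dynamic range =
# max over levels); sex and smoking are likewise single features.

#' Sensitivity profile of one feature
#'
#' Sweeps a feature over a grid while holding all other inputs at the
#' background value (training mean for numeric inputs, zero for binary
#' inputs) and records the model's predicted probability at each grid
#' point.  Numeric features are swept over `grid_size` evenly spaced
#' points between the observed training minimum and maximum (on the
#' model's standardized input scale); binary features over \{0, 1\}; a
#' grouped one-hot block level-by-level.
#'
#' @param model a `trained_model`.
#' @param feature a feature-group name (a lab feature, `"age"`, `"sex"`,
#'   `"smoking"`, or `"stage"`) or a bare column name.
#' @param train_features standardized training feature data frame or
#'   matrix (the scale the model was fit on).
#' @param grid_size number of sweep points for numeric features.
#' @return a `sensitivity_profile`: list with `feature`, `sweep` (data
#'   frame of column, grid value, response) and `dynamic_range`.
#' @export
sensitivity_profile <- function(model, feature, train_features,
                                grid_size = 101) {
  stopifnot(inherits(model, "trained_model"), grid_size >= 2)
  cols_all <- model$feature_names
  groups <- feature_groups(cols_all)
  columns <- if (feature %in% names(groups)) {
    groups[[feature]]
  } else if (feature %in% cols_all) {
    feature
  } else {
    stop("unknown feature: ", feature, call. = FALSE)
  }

  x <- if (is.data.frame(train_features)) {
    feature_matrix(train_features, columns = cols_all)
  } else {
    as.matrix(train_features)[, cols_all, drop = FALSE]
  }
  background <- vapply(cols_all, function(cn) {
    if (is_binary_feature(cn)) 0 else mean(x[, cn])
  }, numeric(1))

  sweeps <- list()
  for (cn in columns) {
    grid <- if (is_binary_feature(cn)) {
      c(0, 1)
    } else {
      seq(min(x[, cn]), max(x[, cn]), length.out = grid_size)
    }
    probe <- matrix(rep(background, each = length(grid)),
                    nrow = length(grid),
                    dimnames = list(NULL, cols_all))
    probe[, cn] <- grid
    sweeps[[cn]] <- data.frame(column = cn, value = grid,
                               response = predict_proba(model, probe),
                               stringsAsFactors = FALSE)
  }
  sweep <- do.call(rbind, sweeps)
  rownames(sweep) <- NULL
  per_col <- vapply(sweeps, function(s) max(s$response) - min(s$response),
                    numeric(1))
  structure(list(feature = feature, columns = columns, sweep = sweep,
                 dynamic_range = max(per_col)),
            class = "sensitivity_profile")
}

#' Recursive feature elimination by response dynamic range
#'
#' At each iteration the model is refit on the full training table with
#' the surviving features, every feature's sensitivity profile is
#' computed, the feature with the smallest dynamic range is removed (ties
#' broken by removing the feature occurring later in the canonical column
#' order), and the cross-validated ROC-AUC and PR-AUC of the surviving
#' set are recorded.  The selected set maximizes (ROC-AUC + PR-AUC)/2
#' along the trace; ties prefer fewer features.
#'
#' @param spec a [model_spec()].
#' @param features raw feature data frame from [extract_features()].
#' @param cv a [cv_spec()]; the same seeded folds are reused at every
#'   feature count.
#' @param groups optional provenance groups for fold assignment.
#' @param grid_size sweep resolution per numeric feature.
#' @return an `rfe_trace`: list with `trace` (data frame: `n_features`,
#'   `eliminated`, `dynamic_range`, `roc_auc`, `pr_auc`), `feature_sets`
#'   (group names per trace row), `selected` (group names) and
#'   `selected_columns`.
#' @export
run_rfe <- function(spec, features, cv = cv_spec(), groups = NULL,
                    grid_size = 101) {
  feature_cols <- setdiff(names(features), c("case_id", "label"))
  current <- feature_groups(feature_cols)
  if (length(current) < 2)
    stop("run_rfe needs at least two features", call. = FALSE)

  canonical <- names(feature_groups(feature_cols))
  trace <- list()
  feature_sets <- list()
  it <- 0
  while (length(current) >= 1) {
    it <- it + 1
    columns <- unname(unlist(current))
    report <- tryCatch(
      cross_validate(spec, features, cv, groups = groups, columns = columns),
      error = function(e) stop(sprintf("cv failure at RFE iteration %d: %s",
                                       it, conditionMessage(e)),
                               call. = FALSE))
    s <- report$summary
    roc <- s$mean[s$metric == "roc_auc"]
    pr <- s$mean[s$metric == "pr_auc"]

    eliminated <- NA_character_
    drange <- NA_real_
    if (length(current) > 1) {
      full <- train_full(spec, features, columns = columns)
      std <- apply_scaler(full$scaler,
                          features[, c("case_id", columns, "label")])
      ranges <- vapply(names(current), function(g)
        sensitivity_profile(full$model, g, std,
                            grid_size = grid_size)$dynamic_range,
        numeric(1))
      weakest <- which(ranges == min(ranges))
      if (length(weakest) > 1) {
        # remove the tied feature occurring later in the canonical order
        weakest <- weakest[which.max(match(names(current)[weakest],
                                           canonical))]
      }
      eliminated <- names(current)[weakest]
      drange <- ranges[weakest]
    }

    feature_sets[[it]] <- names(current)
    trace[[it]] <- data.frame(n_features = length(current),
                              eliminated = eliminated,
                              dynamic_range = unname(drange),
                              roc_auc = roc, pr_auc = pr,
                              stringsAsFactors = FALSE)
    if (length(current) == 1) break
    current <- current[setdiff(names(current), eliminated)]
  }

  trace_df <- do.call(rbind, trace)
  score <- (trace_df$roc_auc + trace_df$pr_auc) / 2
  best <- which(score == max(score))
  best <- best[length(best)]  # ties: fewest features (later trace row)
  selected <- feature_sets[[best]]
  all_groups <- feature_groups(feature_cols)
  structure(list(trace = trace_df, feature_sets = feature_sets,
                 selected = selected,
                 selected_columns = unname(unlist(all_groups[selected])),
                 selection_score = score[best], model = spec$kind),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf("<rfe_trace> %s: %d -> %d features (score %.3f)\n",
              x$model, max(x$trace$n_features), length(x$selected),
              x$selection_score))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Write an RFE trace as CSV
#'
#' Columns mirror the elimination table: features remaining, eliminated
#' feature, dynamic range at removal, ROC-AUC and PR-AUC.
#'
#' @param trace an `rfe_trace`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_rfe_trace <- function(trace, path) {
  write.csv(trace$trace, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
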