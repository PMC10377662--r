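# Four classifiers behind one training/prediction contract.
#
# LR  — maximum-likelihood logistic regression (stats::glm machinery).
# RF  — random forest via ranger: 500 trees, sqrt(p) candidate features.
# GB  — gradient boosting via xgboost: 300 stages, depth 3, shrinkage 0.1.
# DNN — feed-forward network (compiled in this package): hidden layers
#       64/32, ReLU, dropout 0.3, Adam at learning rate 0.001, batch 32,
#       up to 200 epochs with early stopping (patience 20) on a 10%
#       stratified validation split of the training data.
#
# Class imbalance is handled by plain fitting by default; `class_weights`
# can be enabled per spec.

DEFAULT_HYPERPARAMS <- list(
  LR = list(),
  RF = list(num_trees = 500),
  GB = list(nrounds = 300, max_depth = 3, eta = 0.1),
  DNN = list(hidden = c(64L, 32L), dropout = 0.3, learning_rate = 0.001,
             batch_size = 32L, max_epochs = 200L, patience = 20L,
             validation_fraction = 0.1)
)

#' Specify a classifier
#'
#' @param kind one of `"LR"`, `"RF"`, `"GB"`, `"DNN"`.
#' @param seed integer seed for all stochastic components of the fit.
#' @param class_weights if `TRUE`, weight classes inversely to frequency.
#' @param ... hyperparameter overrides (see package defaults above).
#' @return a `model_spec` object.
#' @export
model_spec <- function(kind = c("LR", "RF", "GB", "DNN"), seed = 1L,
                       class_weights = FALSE, ...) {
  kind <- match.arg(kind)
  params <- utils::modifyList(DEFAULT_HYPERPARAMS[[kind]], list(...))
  unknown <- setdiff(names(params), names(DEFAULT_HYPERPARAMS[[kind]]))
  if (length(unknown))
    stop_config(paste(unknown, collapse = ", "),
                sprintf("is not a hyperparameter of kind %s", kind))
  structure(list(kind = kind, seed = as.integer(seed),
                 class_weights = isTRUE(class_weights), params = params),
            class = "model_spec")
}

as_xy <- function(features, label = NULL) {
  if (is.data.frame(features)) {
    if (is.null(label) && "label" %in% names(features))
      label <- features$label
    x <- feature_matrix(features)
  } else {
    x <- as.matrix(features)
  }
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(label))
}

#' Fit a classifier
#'
#' @param spec a [model_spec()].
#' @param features standardized feature data frame (with `label` column)
#'   or numeric matrix with named columns.
#' @param label binary outcome (logical or 0/1); taken from the `label`
#'   column when `features` is a feature data frame.
#' @return a `trained_model` whose feature-name list is bound at fit time;
#'   prediction rejects inputs with a different schema.
#' @export
fit_model <- function(spec, features, label = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- as_xy(features, label)
  x <- xy$x
  y <- xy$y
  if (anyNA(x) || any(!is.finite(x)))
    stop("training features contain missing or non-finite values",
         call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class; cannot fit", call. = FALSE)

  weights <- rep(1, length(y))
  if (spec$class_weights) {
    tab <- table(y)
    weights <- as.numeric(length(y) / (2 * tab[as.character(y)]))
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  fitted <- switch(spec$kind,
    LR = fit_lr(x, y, weights),
    RF = fit_rf(x, y, weights, spec),
    GB = fit_gb(x, y, weights, spec),
    DNN = fit_dnn(x, y, weights, spec)
  )
  structure(list(spec = spec, fitted = fitted, feature_names = colnames(x)),
            class = "trained_model")
}

fit_lr <- function(x, y, weights) {
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, x), y, weights = weights,
            family = binomial())
  )
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # aliased (e.g. constant) columns drop out
  list(coefficients = coefs)
}

fit_rf <- function(x, y, weights, spec) {
  df <- as.data.frame(x)
  df$.outcome <- factor(y, levels = c(0, 1))
  ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    probability = TRUE, num.trees = spec$params$num_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    case.weights = weights,
    seed = spec$seed, num.threads = 1
  )
}

fit_gb <- function(x, y, weights, spec) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = weights)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = spec$params$max_depth,
                  eta = spec$params$eta,
                  nthread = 1, seed = spec$seed),
    data = dtrain, nrounds = spec$params$nrounds, verbose = 0
  )
}

fit_dnn <- function(x, y, weights, spec) {
  p <- spec$params
  n <- length(y)
  # identically-zero columns (e.g. an unobserved one-hot level) carry no
  # signal and no gradient; prune them so they cannot perturb the
  # initialisation stream, and reinsert at prediction time
  active <- which(colSums(abs(x)) > 0)
  x <- x[, active, drop = FALSE]
  # stratified hold-out for early stopping; fall back to monitoring the
  # training loss when a class is too small to spare a row
  val_idx <- integer(0)
  n_val1 <- floor(sum(y == 1) * p$validation_fraction)
  n_val0 <- floor(sum(y == 0) * p$validation_fraction)
  if (n_val1 >= 1 && n_val0 >= 1) {
    val_idx <- c(sample(which(y == 1), n_val1), sample(which(y == 0), n_val0))
  }
  if (length(val_idx)) {
    xtr <- x[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
    xmon <- x[val_idx, , drop = FALSE]; ymon <- y[val_idx]
  } else {
    xtr <- x; ytr <- y; xmon <- x; ymon <- y
  }
  net <- mlp_fit_cpp(xtr, ytr, xmon, ymon,
                     hidden = as.integer(p$hidden), dropout = p$dropout,
                     lr = p$learning_rate, batch_size = as.integer(p$batch_size),
                     max_epochs = as.integer(p$max_epochs),
                     patience = as.integer(p$patience))
  net$active <- active
  net
}

#' Predict recurrence probabilities
#'
#' @param model a `trained_model` from [fit_model()].
#' @param features feature data frame or numeric matrix; column names and
#'   order must match the schema bound at fit time.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  x <- if (is.data.frame(features)) {
    missing <- setdiff(model$feature_names, names(features))
    if (length(missing))
      stop("feature schema mismatch, missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    feature_matrix(features, columns = model$feature_names)
  } else {
    x0 <- as.matrix(features)
    if (is.null(colnames(x0)) ||
        !identical(colnames(x0), model$feature_names))
      stop("feature schema mismatch: expected columns [",
           paste(model$feature_names, collapse = ", "), "]", call. = FALSE)
    x0
  }
  storage.mode(x) <- "double"
  p <- switch(model$spec$kind,
    LR = as.numeric(plogis(cbind(1, x) %*% model$fitted$coefficients)),
    RF = {
      pred <- predict(model$fitted, data = as.data.frame(x),
                      num.threads = 1)$predictions
      as.numeric(pred[, "1"])
    },
    GB = as.numeric(predict(model$fitted, xgboost::xgb.DMatrix(x))),
    DNN = as.numeric(mlp_predict_cpp(model$fitted$W, model$fitted$b,
                                     x[, model$fitted$active, drop = FALSE]))
  )
  pmin(pmax(p, 0), 1)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d features (seed %d)\n",
              x$spec$kind, length(x$feature_names), x$spec$seed))
  invisible(x)
}
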