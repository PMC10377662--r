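# Self-describing model artifacts: kind, hyperparameters, seed, bound
# feature names, and the fitted state.  The gradient-boosting booster is
# stored as its raw byte serialization so the artifact survives across
# sessions (external handles do not).

#' Save a trained model to a file
#'
#' @param model a `trained_model` from [fit_model()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  fitted <- model$fitted
  if (model$spec$kind == "GB") fitted <- xgboost::xgb.save.raw(fitted)
  saveRDS(list(format = "nlrtrack_model", version = 1L,
               kind = model$spec$kind, spec = model$spec,
               feature_names = model$feature_names, fitted = fitted),
          path)
  invisible(path)
}

#' Load a trained model from a file
#'
#' @param path file written by [save_model()].
#' @return a `trained_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nlrtrack_model"))
    stop("not an nlrtrack model artifact: ", path, call. = FALSE)
  fitted <- obj$fitted
  if (obj$kind == "GB") fitted <- xgboost::xgb.load.raw(fitted)
  structure(list(spec = obj$spec, fitted = fitted,
                 feature_names = obj$feature_names),
            class = "trained_model")
}
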