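# End-to-end orchestration: simulate/read -> extract -> split -> train ->
# RFE -> evaluate, with all artifacts written to a run directory and a
# manifest recording the configuration and content hashes.

#' Pipeline run configuration
#'
#' Exactly one input source: a simulation config, or paths to cohort CSVs.
#'
#' @param simulation a [sim_config()], or `NULL` when reading files.
#' @param visit_path,case_path cohort CSVs, or `NULL` when simulating.
#' @param validation optional held-out source for external validation:
#'   a [sim_config()] or `list(visit_path=, case_path=)`.
#' @param windows a [window_config()].
#' @param split_margin_days temporal-split margin (default 180).
#' @param models character subset of `c("LR","RF","GB","DNN")`.
#' @param cv_folds folds for cross-validation.
#' @param rfe_model model kind to run RFE on, or `NULL` to skip.
#' @param rfe_variant `"original"` or `"split"`: feature table RFE uses.
#' @param out_dir output directory (created; must not pre-exist).
#' @param seed single run seed fanned out to every stage.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, visit_path = NULL, case_path = NULL,
                       validation = NULL,
                       windows = window_config(), split_margin_days = 180,
                       models = c("LR", "RF", "GB", "DNN"),
                       cv_folds = 10, rfe_model = NULL,
                       rfe_variant = c("split", "original"),
                       out_dir = tempfile("nlrtrack_run_"), seed = 1L) {
  have_sim <- !is.null(simulation)
  have_files <- !is.null(visit_path) || !is.null(case_path)
  if (have_sim == have_files)
    stop_config("simulation/visit_path",
                "exactly one input source (simulation or files) is required")
  models <- match.arg(models, several.ok = TRUE)
  rfe_variant <- match.arg(rfe_variant)
  if (!is.null(rfe_model)) rfe_model <- match.arg(rfe_model,
                                                  c("LR", "RF", "GB", "DNN"))
  structure(list(simulation = simulation, visit_path = visit_path,
                 case_path = case_path, validation = validation,
                 windows = windows, split_margin_days = split_margin_days,
                 models = models, cv_folds = cv_folds,
                 rfe_model = rfe_model, rfe_variant = rfe_variant,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(log_path, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  cat(line, "\n", file = log_path, sep = "", append = TRUE)
  invisible(line)
}

variant_features <- function(cohort, windows, log_path, tag) {
  ext <- extract_features(cohort, windows)
  if (nrow(ext$exclusions)) {
    counts <- table(ext$exclusions$reason)
    for (r in names(counts))
      log_line(log_path, "INFO",
               sprintf("%s: excluded %d case(s): %s", tag, counts[[r]], r))
  } else {
    log_line(log_path, "INFO", sprintf("%s: no exclusions", tag))
  }
  ext
}

#' Run the full analysis pipeline
#'
#' Writes, under `config$out_dir`: the cohort tables (original and
#' split-augmented, with provenance), feature matrices and exclusion
#' logs for both variants, per-model cross-validation reports, an
#' optional RFE trace, an optional external-validation matrix, a run log,
#' and a `manifest.json` with the configuration and per-artifact MD5
#' hashes.  Reruns with identical config and seed reproduce all
#' deterministic artifacts bit-identically.  On stage failure, partial
#' outputs are retained next to a `FAILED` marker naming the stage.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  stage <- "setup"
  artifacts <- character(0)
  add <- function(...) artifacts <<- c(artifacts, file.path(out, c(...)))

  result <- tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(config$simulation)) {
      log_line(log_path, "INFO", "generating synthetic cohort")
      generate_cohort(config$simulation)
    } else {
      log_line(log_path, "INFO", "reading cohort from files")
      read_cohort(config$visit_path, config$case_path)
    }
    write_cohort(cohort, file.path(out, "cohort_visits.csv"),
                 file.path(out, "cohort_cases.csv"))
    add("cohort_visits.csv", "cohort_cases.csv", "cohort_cases_meta.json")

    stage <- "split"
    split <- split_cohort(cohort, margin_days = config$split_margin_days,
                          windows = config$windows)
    write_cohort(split, file.path(out, "split_visits.csv"),
                 file.path(out, "split_cases.csv"))
    write.csv(split$metadata$provenance, file.path(out, "provenance.csv"),
              row.names = FALSE, quote = FALSE)
    add("split_visits.csv", "split_cases.csv", "split_cases_meta.json",
        "provenance.csv")
    log_line(log_path, "INFO",
             sprintf("split augmentation: %d derived case(s)",
                     nrow(split$metadata$provenance)))

    stage <- "features"
    ext <- list(original = variant_features(cohort, config$windows,
                                            log_path, "original"),
                split = variant_features(split, config$windows,
                                         log_path, "split"))
    for (v in names(ext)) {
      write.csv(ext[[v]]$features, file.path(out, sprintf("features_%s.csv", v)),
                row.names = FALSE, quote = FALSE)
      write.csv(ext[[v]]$exclusions,
                file.path(out, sprintf("exclusions_%s.csv", v)),
                row.names = FALSE, quote = FALSE)
      add(sprintf("features_%s.csv", v), sprintf("exclusions_%s.csv", v))
    }
    groups <- provenance_groups(split)

    stage <- "evaluate"
    cv <- cv_spec(n_folds = config$cv_folds,
                  seed = derive_seed(config$seed, 0L, 0L))
    cv_rows <- list()
    for (v in names(ext)) {
      g <- if (v == "split") groups else NULL
      for (kind in config$models) {
        spec <- model_spec(kind, seed = derive_seed(
          config$seed, match(kind, names(DEFAULT_HYPERPARAMS)), 0L))
        rep <- cross_validate(spec, ext[[v]]$features, cv, groups = g)
        cv_rows[[length(cv_rows) + 1]] <-
          cbind(variant = v, model = kind, rep$folds)
        s <- rep$summary
        log_line(log_path, "INFO", sprintf(
          "%s/%s: ROC-AUC %.3f +/- %.3f, PR-AUC %.3f +/- %.3f",
          v, kind, s$mean[s$metric == "roc_auc"], s$sd[s$metric == "roc_auc"],
          s$mean[s$metric == "pr_auc"], s$sd[s$metric == "pr_auc"]))
      }
    }
    cv_df <- do.call(rbind, cv_rows)
    write.csv(cv_df, file.path(out, "cv_report.csv"),
              row.names = FALSE, quote = FALSE, na = "")
    add("cv_report.csv")

    stage <- "rfe"
    if (!is.null(config$rfe_model)) {
      spec <- model_spec(config$rfe_model, seed = derive_seed(
        config$seed, match(config$rfe_model, names(DEFAULT_HYPERPARAMS)), 500L))
      g <- if (config$rfe_variant == "split") groups else NULL
      rfe <- run_rfe(spec, ext[[config$rfe_variant]]$features, cv, groups = g)
      write_rfe_trace(rfe, file.path(out, "rfe_trace.csv"))
      add("rfe_trace.csv")
      log_line(log_path, "INFO", sprintf(
        "RFE (%s, %s variant): selected %d feature(s): %s",
        config$rfe_model, config$rfe_variant, length(rfe$selected),
        paste(rfe$selected, collapse = ", ")))
    }

    stage <- "external_validation"
    if (!is.null(config$validation)) {
      vcohort <- if (inherits(config$validation, "sim_config")) {
        generate_cohort(config$validation)
      } else {
        read_cohort(config$validation$visit_path, config$validation$case_path)
      }
      vsplit <- split_cohort(vcohort, margin_days = config$split_margin_days,
                             windows = config$windows)
      vext <- list(original = variant_features(vcohort, config$windows,
                                               log_path, "validation original"),
                   split = variant_features(vsplit, config$windows,
                                            log_path, "validation split"))
      ev_rows <- list()
      for (kind in config$models) {
        spec <- model_spec(kind, seed = derive_seed(
          config$seed, match(kind, names(DEFAULT_HYPERPARAMS)), 900L))
        trained <- lapply(ext, function(e)
          train_full(spec, e$features))
        ev_rows[[length(ev_rows) + 1]] <- external_validate(
          trained, lapply(vext, `[[`, "features"))
      }
      ev <- do.call(rbind, ev_rows)
      write.csv(ev, file.path(out, "external_validation.csv"),
                row.names = FALSE, quote = FALSE, na = "")
      add("external_validation.csv")
    }

    stage <- "manifest"
    cfg_list <- unclass(config)
    cfg_list$out_dir <- NULL  # scientific identity only, not placement
    cfg_json <- jsonlite::toJSON(rapply(cfg_list, unclass, how = "replace"),
                                 auto_unbox = TRUE, digits = NA,
                                 null = "null", force = TRUE)
    cfg_path <- file.path(out, "config.json")
    writeLines(cfg_json, cfg_path)
    artifacts <- unique(c(file.path(out, "config.json"), artifacts))
    hashes <- tools::md5sum(artifacts[file.exists(artifacts)])
    manifest <- list(seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_path)),
                     artifacts = as.list(hashes))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(log_path, "INFO", "pipeline complete")
    out
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out, "FAILED"))
    log_line(log_path, "ERROR",
             sprintf("stage %s failed: %s", stage, conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
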