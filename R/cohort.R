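#' Construct a surveillance cohort
#'
#' A cohort bundles a per-case clinical table and a per-visit laboratory
#' table, keyed by `patient_id`, with all times expressed as integer days
#' since the end of treatment (day 0).
#'
#' @param cases data frame with columns `patient_id`, `age`, `sex`
#'   (male/female), `smoking` (yes/no), `stage` (I-IV), `recurrence`
#'   (logical), `recurrence_day` (integer, `NA` unless recurrent),
#'   `followup_end_day` (integer).
#' @param visits data frame with columns `patient_id`, `day`,
#'   `neutrophils`, `lymphocytes`, `platelets` (counts per uL).
#' @param metadata optional list (generator config, seed, provenance ...).
#' @param validate run invariant checks (default `TRUE`).
#' @return an object of class `nlr_cohort`.
#' @export
new_cohort <- function(cases, visits, metadata = list(), validate = TRUE) {
  cases <- as.data.frame(cases)[, CASE_COLS, drop = FALSE]
  visits <- as.data.frame(visits)[, VISIT_COLS, drop = FALSE]
  # canonical order: cases by id; visits by id, then day
  cases <- cases[order(cases$patient_id), , drop = FALSE]
  visits <- visits[order(visits$patient_id, visits$day), , drop = FALSE]
  rownames(cases) <- rownames(visits) <- NULL
  obj <- structure(list(cases = cases, visits = visits, metadata = metadata),
                   class = "nlr_cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks referential integrity and the per-case invariants: unique ids,
#' strictly increasing visit days, positive finite counts, recurrence day
#' present iff recurrent and greater than 90 days (earlier events count as
#' remnant disease, not recurrence), and follow-up end not before the last
#' visit.
#'
#' @param cohort an `nlr_cohort`.
#' @return the cohort, invisibly; stops with a descriptive error otherwise.
#' @export
validate_cohort <- function(cohort) {
  cases <- cohort$cases
  visits <- cohort$visits
  if (anyDuplicated(cases$patient_id))
    stop("validation error: duplicate patient_id in case table: ",
         paste(unique(cases$patient_id[duplicated(cases$patient_id)]),
               collapse = ", "), call. = FALSE)
  orphan <- setdiff(unique(visits$patient_id), cases$patient_id)
  if (length(orphan))
    stop("validation error: visit rows reference unknown patient_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  bad_sex <- !cases$sex %in% c("male", "female")
  bad_smoke <- !cases$smoking %in% c("yes", "no")
  bad_stage <- !cases$stage %in% STAGE_LEVELS
  if (any(bad_sex | bad_smoke | bad_stage))
    stop("validation error: invalid category level(s) in case rows ",
         paste(which(bad_sex | bad_smoke | bad_stage), collapse = ", "),
         call. = FALSE)
  rec <- cases$recurrence
  if (any(rec & is.na(cases$recurrence_day)))
    stop("validation error: recurrent case without recurrence_day: rows ",
         paste(which(rec & is.na(cases$recurrence_day)), collapse = ", "),
         call. = FALSE)
  if (any(!rec & !is.na(cases$recurrence_day)))
    stop("validation error: non-recurrent case with recurrence_day: rows ",
         paste(which(!rec & !is.na(cases$recurrence_day)), collapse = ", "),
         call. = FALSE)
  if (any(cases$recurrence_day[rec] <= 90))
    stop("validation error: recurrence_day must exceed 90 days ",
         "(remnant-disease exclusion): rows ",
         paste(which(rec)[cases$recurrence_day[rec] <= 90], collapse = ", "),
         call. = FALSE)
  counts <- as.matrix(visits[, c("neutrophils", "lymphocytes", "platelets")])
  if (nrow(visits) > 0 && (any(!is.finite(counts)) || any(counts <= 0)))
    stop("validation error: non-positive or non-finite counts in visit rows ",
         paste(which(rowSums(!is.finite(counts) | counts <= 0) > 0),
               collapse = ", "), call. = FALSE)
  if (nrow(visits) > 0) {
    dup <- duplicated(visits[, c("patient_id", "day")])
    if (any(dup))
      stop("validation error: duplicate (patient_id, day) in visit rows ",
           paste(which(dup), collapse = ", "), call. = FALSE)
    last <- tapply(visits$day, visits$patient_id, max)
    fe <- setNames(cases$followup_end_day, cases$patient_id)
    late <- names(last)[last > fe[names(last)]]
    if (length(late))
      stop("validation error: followup_end_day before last visit for: ",
           paste(late, collapse = ", "), call. = FALSE)
  }
  invisible(cohort)
}

#' @export
print.nlr_cohort <- function(x, ...) {
  n <- nrow(x$cases)
  nrec <- sum(x$cases$recurrence)
  cat(sprintf("<nlr_cohort> %d cases (%d recurrent, %.1f%%), %d visits\n",
              n, nrec, if (n) 100 * nrec / n else 0, nrow(x$visits)))
  if (!is.null(x$metadata$seed))
    cat(sprintf("  generator seed: %s\n", x$metadata$seed))
  if (!is.null(x$metadata$provenance))
    cat(sprintf("  split-augmented: %d derived cases\n",
                nrow(x$metadata$provenance)))
  invisible(x)
}

empty_visit_table <- function() {
  data.frame(patient_id = character(0), day = integer(0),
             neutrophils = numeric(0), lymphocytes = numeric(0),
             platelets = numeric(0), stringsAsFactors = FALSE)
}

empty_case_table <- function() {
  data.frame(patient_id = character(0), age = numeric(0), sex = character(0),
             smoking = character(0), stage = character(0),
             recurrence = logical(0), recurrence_day = integer(0),
             followup_end_day = integer(0), stringsAsFactors = FALSE)
}
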