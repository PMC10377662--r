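# Cohort serialization: two CSV tables plus a JSON metadata sidecar.
# Days are integers relative to treatment end (day 0); an optional
# date-mode reader converts ISO-8601 calendar dates using a per-case
# treatment-end date column.

SCHEMA_VERSION <- "1.0"

#' Write a cohort to CSV tables
#'
#' Writes the visit and case tables as UTF-8 comma-separated text with a
#' deterministic row order (by `patient_id`, then `day`) and column order.
#' A missing `recurrence_day` is serialized as an empty field.  Metadata
#' (generator config, seed, schema version) is written to a JSON sidecar
#' next to the case table.
#'
#' @param cohort an `nlr_cohort`.
#' @param visit_path,case_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, visit_path, case_path) {
  validate_cohort(cohort)
  visits <- cohort$visits[order(cohort$visits$patient_id, cohort$visits$day), ,
                          drop = FALSE]
  cases <- cohort$cases[order(cohort$cases$patient_id), , drop = FALSE]
  write.csv(visits, visit_path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8", na = "")
  write.csv(cases, case_path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8", na = "")
  meta <- cohort$metadata %||% list()
  meta$schema_version <- SCHEMA_VERSION
  sidecar <- paste0(sub("\\.csv$", "", case_path), "_meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(visit_path = visit_path, case_path = case_path,
              metadata_path = sidecar))
}

#' Read a cohort from CSV tables
#'
#' Inverse of [write_cohort()].  Validates headers against the documented
#' schema, attaches every visit row to an existing case, and re-checks all
#' cohort invariants.  In date mode, visit `date` and per-case
#' `treatment_end_date` columns (ISO-8601) are converted to integer day
#' offsets from treatment end.
#'
#' @param visit_path,case_path input file paths.
#' @param date_mode if `TRUE`, expect calendar-date columns instead of
#'   integer `day` offsets.
#' @return an `nlr_cohort`.
#' @export
read_cohort <- function(visit_path, case_path, date_mode = FALSE) {
  for (p in c(visit_path, case_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  visits <- read.csv(visit_path, stringsAsFactors = FALSE,
                     fileEncoding = "UTF-8")
  cases <- read.csv(case_path, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")

  want_visit <- if (date_mode) {
    c("patient_id", "date", "neutrophils", "lymphocytes", "platelets")
  } else {
    VISIT_COLS
  }
  want_case <- if (date_mode) {
    c(setdiff(CASE_COLS, c("recurrence_day", "followup_end_day")),
      "treatment_end_date", "recurrence_date", "followup_end_date")
  } else {
    CASE_COLS
  }
  check_schema("visit table", names(visits), want_visit)
  check_schema("case table", names(cases), want_case)

  if (date_mode) {
    t0 <- as.Date(cases$treatment_end_date)
    if (anyNA(t0)) stop("format error: unparseable treatment_end_date",
                        call. = FALSE)
    origin <- setNames(t0, cases$patient_id)
    known <- visits$patient_id %in% cases$patient_id
    if (!all(known))
      stop("validation error: visit rows reference unknown patient_id: ",
           paste(unique(visits$patient_id[!known]), collapse = ", "),
           call. = FALSE)
    visits$day <- as.integer(as.Date(visits$date) -
                               origin[visits$patient_id])
    visits$date <- NULL
    cases$recurrence_day <- ifelse(
      is.na(cases$recurrence_date) | cases$recurrence_date == "",
      NA_integer_,
      as.integer(as.Date(cases$recurrence_date) - t0))
    cases$followup_end_day <- as.integer(as.Date(cases$followup_end_date) - t0)
    cases$treatment_end_date <- NULL
    cases$recurrence_date <- NULL
    cases$followup_end_date <- NULL
  }

  cases$recurrence <- as.logical(cases$recurrence)
  cases$recurrence_day <- suppressWarnings(as.integer(cases$recurrence_day))
  cases$followup_end_day <- as.integer(cases$followup_end_day)
  visits$day <- as.integer(visits$day)

  meta <- list()
  sidecar <- paste0(sub("\\.csv$", "", case_path), "_meta.json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  new_cohort(cases, visits, metadata = meta)
}

check_schema <- function(what, have, want) {
  missing <- setdiff(want, have)
  unknown <- setdiff(have, want)
  if (length(missing) || length(unknown))
    stop(sprintf("format error in %s: missing columns [%s], unknown columns [%s]",
                 what, paste(missing, collapse = ", "),
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
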