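# Temporal-split data augmentation.
#
# The interval between tumour initiation and overt presentation is taken to
# be at most about six months, so laboratory values recorded more than
# `margin_days` (default 180) before the detection of a recurrence are
# treated as measurements of a non-recurrent state.  Each eligible
# recurrent case therefore contributes one additional derived case: its
# early trajectory segment, relabelled non-recurrent.

#' Augment a cohort by temporal splitting of recurrent cases
#'
#' For every recurrent case whose detection day lies more than
#' `margin_days` after treatment end, and whose early segment (visits at
#' day <= detection - margin) still supports feature extraction (at least
#' `min_visits` post-treatment visits, one of them inside the Tx window),
#' a derived non-recurrent case is appended: visits truncated to the early
#' segment, `followup_end_day` set to detection - margin, clinical
#' covariates copied, id suffixed with `".s"`.  Original cases pass
#' through unchanged.
#'
#' @param cohort an `nlr_cohort`.
#' @param margin_days split margin in days before detection (default 180).
#' @param min_visits minimum early-segment visits for eligibility.
#' @param windows a [window_config()]; used for the Tx-window eligibility
#'   check so derived cases are not excluded downstream.
#' @return an `nlr_cohort` whose metadata carries a `provenance` data frame
#'   (`derived_id`, `parent_id`, `split_day`).
#' @export
split_cohort <- function(cohort, margin_days = 180, min_visits = 2,
                         windows = window_config()) {
  if (!is.numeric(margin_days) || margin_days <= 0)
    stop_config("margin_days", "must be a positive number of days")
  validate_cohort(cohort)

  cases <- cohort$cases
  visits <- cohort$visits
  derived_cases <- list()
  derived_visits <- list()
  prov <- list()

  rec_idx <- which(cases$recurrence)
  for (i in rec_idx) {
    case <- cases[i, ]
    split_day <- case$recurrence_day - margin_days
    if (split_day <= 0) next  # recurred within the margin after treatment
    early <- visits[visits$patient_id == case$patient_id &
                      visits$day >= 0 & visits$day <= split_day, ,
                    drop = FALSE]
    if (nrow(early) < min_visits) next
    if (!any(early$day >= windows$tx_lo & early$day <= windows$tx_hi)) next

    new_id <- paste0(case$patient_id, ".s")
    if (new_id %in% cases$patient_id) next  # already split: idempotence
    dcase <- case
    dcase$patient_id <- new_id
    dcase$recurrence <- FALSE
    dcase$recurrence_day <- NA_integer_
    dcase$followup_end_day <- as.integer(split_day)
    early$patient_id <- new_id

    derived_cases[[length(derived_cases) + 1]] <- dcase
    derived_visits[[length(derived_visits) + 1]] <- early
    prov[[length(prov) + 1]] <- data.frame(
      derived_id = new_id, parent_id = case$patient_id,
      split_day = as.integer(split_day), stringsAsFactors = FALSE)
  }

  provenance <- if (length(prov)) {
    do.call(rbind, prov)
  } else {
    data.frame(derived_id = character(0), parent_id = character(0),
               split_day = integer(0), stringsAsFactors = FALSE)
  }
  meta <- cohort$metadata %||% list()
  meta$provenance <- provenance
  meta$split_margin_days <- margin_days

  new_cohort(rbind(cases, do.call(rbind, derived_cases)),
             rbind(visits, do.call(rbind, derived_visits)),
             metadata = meta)
}

#' Provenance groups for leakage-free fold assignment
#'
#' Partitions case ids so that every derived case shares a group with its
#' parent patient; cases without derivations form singleton groups.  Used
#' for group-aware cross-validation fold assignment.
#'
#' @param cohort an `nlr_cohort`, typically from [split_cohort()].
#' @return named character vector mapping case id to group id (the parent
#'   patient id).
#' @export
provenance_groups <- function(cohort) {
  ids <- cohort$cases$patient_id
  groups <- setNames(ids, ids)
  prov <- cohort$metadata$provenance
  if (!is.null(prov) && nrow(prov) > 0)
    groups[prov$derived_id] <- prov$parent_id
  groups
}
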