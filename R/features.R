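# Windowed NLR/PLR meta-features.
#
# Twelve laboratory meta-features per case, six per ratio:
#   *_mean   mean of per-visit ratios over the whole observation horizon
#   *_maxmin max minus min of per-visit ratios over the horizon
#   *_Tx     mean ratio in the post-treatment window (day 14..90)
#   *_R      mean ratio in the recurrence window (detection day -90..+30)
#            for recurrent cases; the ratio at the last observed visit for
#            non-recurrent cases
#   *_Rmean  *_R - *_mean
#   *_RTx    *_R - *_Tx
# plus age, sex, smoking and one-hot stage.  All windows are closed
# integer-day intervals; visits before day 0 are never used.

#' Window configuration for meta-feature extraction
#'
#' @param tx_lo,tx_hi post-treatment window bounds, days after treatment
#'   end (default 14..90).
#' @param r_lo,r_hi recurrence window bounds relative to the detection day
#'   (default -90..+30).
#' @param followup_cap observation cap in days (default 1825 = 5 years).
#' @param window_aggregate how to summarise multiple visits inside the Tx
#'   or R window: `"mean"` (default) or `"closest"` (value at the visit
#'   closest to the window anchor: treatment end for Tx, detection day for R).
#' @return a `window_config` list.
#' @export
window_config <- function(tx_lo = 14, tx_hi = 90, r_lo = -90, r_hi = 30,
                          followup_cap = 1825,
                          window_aggregate = c("mean", "closest")) {
  window_aggregate <- match.arg(window_aggregate)
  if (!(tx_lo < tx_hi)) stop_config("tx_lo/tx_hi", "must satisfy tx_lo < tx_hi")
  if (!(r_lo < 0 && r_hi > 0))
    stop_config("r_lo/r_hi", "must satisfy r_lo < 0 < r_hi")
  if (followup_cap <= 0) stop_config("followup_cap", "must be positive")
  structure(list(tx_lo = tx_lo, tx_hi = tx_hi, r_lo = r_lo, r_hi = r_hi,
                 followup_cap = followup_cap,
                 window_aggregate = window_aggregate),
            class = "window_config")
}

#' Neutrophil- and platelet-to-lymphocyte ratios for visit rows
#'
#' @param visits data frame with `neutrophils`, `lymphocytes`, `platelets`
#'   columns (and optionally `patient_id`/`day` for error reporting).
#' @return the input with `nlr` and `plr` columns appended.
#' @export
compute_ratios <- function(visits) {
  bad <- !is.finite(visits$lymphocytes) | visits$lymphocytes <= 0
  if (any(bad)) {
    where <- if (all(c("patient_id", "day") %in% names(visits))) {
      paste(sprintf("%s day %s", visits$patient_id[bad], visits$day[bad]),
            collapse = "; ")
    } else {
      paste("rows", paste(which(bad), collapse = ", "))
    }
    stop("domain error: non-positive lymphocyte count at ", where,
         call. = FALSE)
  }
  visits$nlr <- visits$neutrophils / visits$lymphocytes
  visits$plr <- visits$platelets / visits$lymphocytes
  visits
}

#' Observation horizon of a case
#'
#' The aggregation horizon for the mean and max-min features: the
#' recurrence-detection day for recurrent cases, and the capped follow-up
#' end for non-recurrent cases.  The recurrence window itself may extend
#' up to `r_hi` days past this horizon for recurrent cases.
#'
#' @param case one-row data frame or list with `recurrence`,
#'   `recurrence_day`, `followup_end_day`.
#' @param windows a [window_config()].
#' @return integer day.
#' @export
observation_horizon <- function(case, windows = window_config()) {
  if (isTRUE(case$recurrence)) {
    as.integer(case$recurrence_day)
  } else {
    as.integer(min(case$followup_end_day, windows$followup_cap))
  }
}

window_value <- function(ratios, days, lo, hi, anchor, mode) {
  inside <- days >= lo & days <= hi
  if (!any(inside)) return(NA_real_)
  if (mode == "closest") {
    sel <- which(inside)
    ratios[sel[which.min(abs(days[sel] - anchor))]]
  } else {
    mean(ratios[inside])
  }
}

extract_one_case <- function(case, visits, windows) {
  horizon <- observation_horizon(case, windows)
  rec <- isTRUE(case$recurrence)

  in_scope <- visits$day >= 0 & visits$day <= horizon
  vis <- visits[in_scope, , drop = FALSE]
  if (nrow(vis) < 2) return(list(reason = "TOO_FEW_VISITS"))

  out <- c()
  for (ratio in c("nlr", "plr")) {
    vals <- vis[[ratio]]
    prefix <- toupper(ratio)
    m <- mean(vals)
    mm <- max(vals) - min(vals)
    tx <- window_value(vals, vis$day, windows$tx_lo, windows$tx_hi,
                       anchor = 0, mode = windows$window_aggregate)
    if (rec) {
      # R window is anchored on the detection day and may run past the
      # aggregation horizon, so index the full visit series here
      rv <- window_value(visits[[ratio]], visits$day,
                         case$recurrence_day + windows$r_lo,
                         case$recurrence_day + windows$r_hi,
                         anchor = case$recurrence_day,
                         mode = windows$window_aggregate)
    } else {
      rv <- vals[which.max(vis$day)]  # value at the end of the period
    }
    if (is.na(tx)) return(list(reason = "NO_TX_WINDOW_VISIT"))
    if (is.na(rv)) return(list(reason = "NO_R_WINDOW_VISIT"))
    feats <- c(m, mm, tx, rv, rv - m, rv - tx)
    names(feats) <- paste0(prefix, c("_mean", "_maxmin", "_Tx", "_R",
                                     "_Rmean", "_RTx"))
    out <- c(out, feats)
  }
  list(features = out)
}

#' Extract meta-feature vectors for every case in a cohort
#'
#' Computes the 12 windowed laboratory meta-features and the encoded
#' clinical covariates (age; sex and smoking as 0/1; stage one-hot) for
#' each case.  Cases with fewer than two usable post-treatment visits, or
#' with no visit inside the Tx or R window, are returned as exclusion
#' records with a reason code rather than silently defaulted.
#'
#' @param cohort an `nlr_cohort`.
#' @param windows a [window_config()].
#' @return list with `features` (data frame: `case_id`, the 19 feature
#'   columns in canonical order, `label`) and `exclusions` (data frame:
#'   `case_id`, `reason`).
#' @export
extract_features <- function(cohort, windows = window_config()) {
  validate_cohort(cohort)
  visits <- compute_ratios(cohort$visits)
  by_patient <- split(visits, visits$patient_id)
  cases <- cohort$cases

  feat_rows <- vector("list", nrow(cases))
  excl_rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    vis <- by_patient[[case$patient_id]]
    res <- if (is.null(vis)) {
      list(reason = "TOO_FEW_VISITS")
    } else {
      extract_one_case(case, vis, windows)
    }
    if (!is.null(res$reason)) {
      excl_rows[[i]] <- data.frame(case_id = case$patient_id,
                                   reason = res$reason,
                                   stringsAsFactors = FALSE)
      next
    }
    clin <- c(age = case$age,
              sex_male = as.numeric(case$sex == "male"),
              smoking_yes = as.numeric(case$smoking == "yes"),
              setNames(as.numeric(STAGE_LEVELS == case$stage), STAGE_COLS))
    row <- c(res$features, clin)
    feat_rows[[i]] <- data.frame(case_id = case$patient_id,
                                 t(row[ALL_FEATURES]),
                                 label = case$recurrence,
                                 stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feat_rows[!vapply(feat_rows, is.null, logical(1))])
  exclusions <- do.call(rbind, excl_rows[!vapply(excl_rows, is.null, logical(1))])
  if (is.null(features))
    features <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(ALL_FEATURES)),
        list(logical(0))),
      c("case_id", ALL_FEATURES, "label")))
  if (is.null(exclusions))
    exclusions <- data.frame(case_id = character(0), reason = character(0),
                             stringsAsFactors = FALSE)
  rownames(features) <- rownames(exclusions) <- NULL
  list(features = features, exclusions = exclusions)
}

# Standardization --------------------------------------------------------

#' Fit a feature scaler on training rows
#'
#' Centres and scales the numeric columns (the 12 laboratory meta-features
#' and age) by their training-row mean and population (divide-by-n)
#' standard deviation.  Binary and one-hot columns are passed through.
#' A zero-variance column gets sd 1 with a warning.
#'
#' @param features feature data frame from [extract_features()].
#' @param fit_rows integer/logical index of rows to learn statistics from.
#' @return an `nlr_scaler` holding per-column means and sds.
#' @export
fit_scaler <- function(features, fit_rows = seq_len(nrow(features))) {
  fit <- features[fit_rows, , drop = FALSE]
  if (nrow(fit) == 0) stop("empty fit set for standardization", call. = FALSE)
  cols <- setdiff(names(features), c("case_id", "label"))
  cols <- cols[!is_binary_feature(cols)]
  mu <- vapply(fit[cols], mean, numeric(1))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sigma <- vapply(fit[cols], pop_sd, numeric(1))
  zero <- sigma == 0
  if (any(zero)) {
    warning("zero-variance feature(s) on fit rows, sd set to 1: ",
            paste(cols[zero], collapse = ", "), call. = FALSE)
    sigma[zero] <- 1
  }
  structure(list(columns = cols, mean = mu, sd = sigma),
            class = "nlr_scaler")
}

#' Apply a fitted scaler
#'
#' Applies stored (x - mean) / sd verbatim; never refits.
#'
#' @param scaler an `nlr_scaler` from [fit_scaler()].
#' @param features feature data frame (training or held-out rows).
#' @return the data frame with numeric columns standardized.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "nlr_scaler"))
  missing <- setdiff(scaler$columns, names(features))
  if (length(missing))
    stop("feature schema mismatch, missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in scaler$columns)
    features[[col]] <- (features[[col]] - scaler$mean[[col]]) / scaler$sd[[col]]
  features
}

# numeric feature matrix (drops id/label), preserving canonical order
feature_matrix <- function(features, columns = NULL) {
  cols <- columns %||% setdiff(names(features), c("case_id", "label"))
  as.matrix(features[, cols, drop = FALSE])
}
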