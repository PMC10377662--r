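# Independent reference implementations used as oracles.  These are
# written as naive explicit loops straight from the feature definitions
# and must stay independent of the package's vectorized code paths.

# Naive per-case meta-feature computation: loops over visits, no shared
# helpers with the package.
naive_case_features <- function(case, visits, tx_lo = 14, tx_hi = 90,
                                r_lo = -90, r_hi = 30, cap = 1825) {
  horizon <- if (isTRUE(case$recurrence)) {
    case$recurrence_day
  } else {
    min(case$followup_end_day, cap)
  }
  nlr <- c(); plr <- c(); days <- c()
  for (j in seq_len(nrow(visits))) {
    v <- visits[j, ]
    if (v$day >= 0 && v$day <= horizon) {
      nlr <- c(nlr, v$neutrophils / v$lymphocytes)
      plr <- c(plr, v$platelets / v$lymphocytes)
      days <- c(days, v$day)
    }
  }
  if (length(days) < 2) return(list(reason = "TOO_FEW_VISITS"))

  ratio_at <- function(v, kind) {
    if (kind == "nlr") v$neutrophils / v$lymphocytes
    else v$platelets / v$lymphocytes
  }

  one_ratio <- function(vals, kind) {
    m <- sum(vals) / length(vals)
    mm <- max(vals) - min(vals)
    tx_vals <- c()
    for (i in seq_along(days)) {
      if (days[i] >= tx_lo && days[i] <= tx_hi) tx_vals <- c(tx_vals, vals[i])
    }
    if (length(tx_vals) == 0) return(list(reason = "NO_TX_WINDOW_VISIT"))
    tx <- sum(tx_vals) / length(tx_vals)
    if (isTRUE(case$recurrence)) {
      r_vals <- c()
      for (j in seq_len(nrow(visits))) {
        v <- visits[j, ]
        if (v$day >= case$recurrence_day + r_lo &&
            v$day <= case$recurrence_day + r_hi) {
          r_vals <- c(r_vals, ratio_at(v, kind))
        }
      }
      if (length(r_vals) == 0) return(list(reason = "NO_R_WINDOW_VISIT"))
      r <- sum(r_vals) / length(r_vals)
    } else {
      r <- vals[which(days == max(days))[1]]
    }
    list(values = c(m, mm, tx, r, r - m, r - tx))
  }

  res_n <- one_ratio(nlr, "nlr")
  if (!is.null(res_n$reason)) return(list(reason = res_n$reason))
  res_p <- one_ratio(plr, "plr")
  if (!is.null(res_p$reason)) return(list(reason = res_p$reason))
  out <- c(res_n$values, res_p$values)
  names(out) <- c(paste0("NLR", c("_mean", "_maxmin", "_Tx", "_R",
                                  "_Rmean", "_RTx")),
                  paste0("PLR", c("_mean", "_maxmin", "_Tx", "_R",
                                  "_Rmean", "_RTx")))
  list(values = out)
}

# Brute-force ROC-AUC: all positive/negative pairs, ties count half.
brute_roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Build a small cohort from explicit visit days and NLR/PLR values
# (lymphocytes fixed at 1000 so counts map directly to ratios).
toy_cohort <- function(days, nlr, plr = nlr * 50, recurrence = TRUE,
                       recurrence_day = if (recurrence) 430 else NA,
                       followup_end_day = max(days), id = "T001",
                       age = 60, sex = "male", smoking = "no",
                       stage = "III") {
  cases <- data.frame(
    patient_id = id, age = age, sex = sex, smoking = smoking, stage = stage,
    recurrence = recurrence,
    recurrence_day = as.integer(recurrence_day),
    followup_end_day = as.integer(max(followup_end_day, days)),
    stringsAsFactors = FALSE
  )
  visits <- data.frame(
    patient_id = id, day = as.integer(days),
    neutrophils = 1000 * nlr, lymphocytes = 1000, platelets = 1000 * plr,
    stringsAsFactors = FALSE
  )
  new_cohort(cases, visits)
}

# Synthetic tabular feature frame (not cohort-derived) for model and RFE
# tests: numeric features with an optional planted logistic signal.
toy_feature_frame <- function(n, p, beta = rep(0, p), intercept = 0,
                              seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- intercept + x %*% beta
  y <- runif(n) < plogis(eta)
  df <- data.frame(case_id = sprintf("C%04d", seq_len(n)), x,
                   stringsAsFactors = FALSE)
  df$label <- as.logical(y)
  df
}

# Hand-rolled LR trained_model with fixed coefficients, for closed-form
# sensitivity checks.
manual_lr_model <- function(coefficients, feature_names) {
  structure(list(
    spec = model_spec("LR"),
    fitted = list(coefficients = c(`(Intercept)` = coefficients[1],
                                   setNames(coefficients[-1], feature_names))),
    feature_names = feature_names
  ), class = "trained_model")
}
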