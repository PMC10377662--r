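#' Simulation configuration for synthetic surveillance cohorts
#'
#' Builds and validates the parameter set of the synthetic cohort generator.
#' The generator emulates post-chemoradiotherapy surveillance data for head
#' and neck cancer: irregular clinic visits, transient treatment-induced
#' lymphopenia, and — for recurrent cases — a multiplicative ramp in the
#' blood counts over the months preceding recurrence detection.
#'
#' Defaults reproduce the demographic structure of a typical definitive-CCRT
#' cohort (mean age 60.4 (SD 13.0) years, ~80% male, ~62% smokers, stage
#' distribution heavily weighted to III/IV, 26.5% recurrence prevalence,
#' 5-year follow-up cap).  All lab-value distributions are simulation
#' choices; the surveillance literature reports only the derived ratios.
#'
#' @param n_patients number of synthetic cases.
#' @param recurrence_prob probability a case recurs (Bernoulli label).
#' @param visit_interval_mean_days,visit_interval_sd_days mean/SD of the
#'   gamma-distributed inter-visit intervals (days).
#' @param followup_cap_days follow-up horizon (days, default 5 years).
#' @param baseline_log_means,baseline_log_sds named numeric vectors
#'   (`neutrophils`, `lymphocytes`, `platelets`): log-scale patient-level
#'   baseline count distributions (cells/uL).
#' @param lymphopenia_depth fraction in \[0,1): lymphocyte suppression at
#'   treatment end (0.5 = halved).
#' @param lymphopenia_recovery_days exponential recovery timescale (days).
#' @param ramp_onset_days days before recurrence detection at which the
#'   recurrence effect starts (default 180).
#' @param effect_neut,effect_plt multiplicative fold-change (>= 1) of
#'   neutrophils/platelets at the moment of detection.
#' @param effect_lymph multiplicative fold-change in (0, 1\] of lymphocytes
#'   at detection.
#' @param noise_sd_log SD of the per-visit lognormal measurement noise.
#' @param age_mean,age_sd age distribution (years).
#' @param male_frac,smoking_frac covariate prevalences.
#' @param stage_probs length-4 probability vector over stages I-IV.
#' @param recurrence_shape,recurrence_scale Weibull parameters of the
#'   recurrence-detection day, truncated to (90, cap\].
#' @param censoring `"matched"` (default) draws a pseudo-event day for
#'   non-recurrent cases from the same truncated Weibull used for
#'   recurrence detection and censors there, so the observation schedule
#'   carries no label information; `"uniform"` censors uniformly between
#'   `censor_min_days` and the cap (wider follow-up spread, but follow-up
#'   length then correlates with the label).
#' @param censor_min_days earliest censoring day under uniform censoring.
#' @param first_visit_range first visit drawn uniformly in this day range.
#' @param seed integer RNG seed recorded in the cohort metadata.
#' @return a validated `sim_config` object (list).
#' @export
sim_config <- function(n_patients = 778,
                       recurrence_prob = 0.265,
                       visit_interval_mean_days = 60,
                       visit_interval_sd_days = 35,
                       followup_cap_days = 1825,
                       baseline_log_means = c(neutrophils = log(4000),
                                              lymphocytes = log(1800),
                                              platelets = log(250000)),
                       baseline_log_sds = c(neutrophils = 0.25,
                                            lymphocytes = 0.25,
                                            platelets = 0.2),
                       lymphopenia_depth = 0.5,
                       lymphopenia_recovery_days = 180,
                       ramp_onset_days = 180,
                       effect_neut = 1.5,
                       effect_plt = 1.5,
                       effect_lymph = 0.75,
                       noise_sd_log = 0.15,
                       age_mean = 60.4,
                       age_sd = 13.0,
                       male_frac = 625 / 778,
                       smoking_frac = 0.618,
                       stage_probs = c(11, 68, 209, 489) / 777,
                       recurrence_shape = 1.2,
                       recurrence_scale = 900,
                       censoring = c("matched", "uniform"),
                       censor_min_days = 365,
                       first_visit_range = c(14, 90),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    recurrence_prob = recurrence_prob,
    visit_interval_mean_days = visit_interval_mean_days,
    visit_interval_sd_days = visit_interval_sd_days,
    followup_cap_days = followup_cap_days,
    baseline_log_means = baseline_log_means,
    baseline_log_sds = baseline_log_sds,
    lymphopenia_depth = lymphopenia_depth,
    lymphopenia_recovery_days = lymphopenia_recovery_days,
    ramp_onset_days = ramp_onset_days,
    effect_neut = effect_neut,
    effect_plt = effect_plt,
    effect_lymph = effect_lymph,
    noise_sd_log = noise_sd_log,
    age_mean = age_mean,
    age_sd = age_sd,
    male_frac = male_frac,
    smoking_frac = smoking_frac,
    stage_probs = stage_probs,
    recurrence_shape = recurrence_shape,
    recurrence_scale = recurrence_scale,
    censoring = match.arg(censoring),
    censor_min_days = censor_min_days,
    first_visit_range = first_visit_range,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_patients", "visit_interval_mean_days", "visit_interval_sd_days",
           "followup_cap_days", "lymphopenia_recovery_days", "ramp_onset_days",
           "recurrence_shape", "recurrence_scale", "censor_min_days",
           "age_sd")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
        !is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop_config(f, "must be a single positive number")
  }
  for (f in c("recurrence_prob", "male_frac", "smoking_frac")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config(f, "must be a probability in [0, 1]")
  }
  if (length(cfg$stage_probs) != 4 || any(cfg$stage_probs < 0) ||
      abs(sum(cfg$stage_probs) - 1) > 1e-9)
    stop_config("stage_probs", "must be 4 nonnegative values summing to 1")
  if (cfg$lymphopenia_depth < 0 || cfg$lymphopenia_depth >= 1)
    stop_config("lymphopenia_depth", "must lie in [0, 1)")
  if (cfg$effect_neut < 1) stop_config("effect_neut", "must be >= 1")
  if (cfg$effect_plt < 1) stop_config("effect_plt", "must be >= 1")
  if (cfg$effect_lymph <= 0 || cfg$effect_lymph > 1)
    stop_config("effect_lymph", "must lie in (0, 1]")
  if (cfg$noise_sd_log < 0) stop_config("noise_sd_log", "must be >= 0")
  lab <- c("neutrophils", "lymphocytes", "platelets")
  if (!all(lab %in% names(cfg$baseline_log_means)))
    stop_config("baseline_log_means", "must name neutrophils, lymphocytes, platelets")
  if (!all(lab %in% names(cfg$baseline_log_sds)) ||
      any(cfg$baseline_log_sds[lab] <= 0))
    stop_config("baseline_log_sds", "must be positive for all three counts")
  if (length(cfg$first_visit_range) != 2 ||
      cfg$first_visit_range[1] < 0 ||
      cfg$first_visit_range[1] >= cfg$first_visit_range[2])
    stop_config("first_visit_range", "must be an increasing day range")
  invisible(cfg)
}

# Noise-free mean trajectory components ---------------------------------

#' Deterministic mean blood counts along a simulated trajectory
#'
#' Exposes the noise-free mean components of the generator: patient baseline
#' x lymphopenia recovery factor (lymphocytes only) x recurrence ramp factor
#' (recurrent cases only, log-linear from 1 at ramp onset to the configured
#' effect at the detection day, held constant afterwards).
#'
#' @param case a list/row with `recurrence` and `recurrence_day`; baselines
#'   taken from `baselines` (named vector, counts/uL) or the config means.
#' @param day day since treatment end.
#' @param config a [sim_config()].
#' @param baselines optional named vector of patient baseline counts.
#' @return named numeric vector (neutrophils, lymphocytes, platelets).
#' @export
trajectory_value <- function(case, day, config, baselines = NULL) {
  if (is.null(baselines)) baselines <- exp(config$baseline_log_means)
  lymp_factor <- 1 - config$lymphopenia_depth *
    exp(-pmax(day, 0) / config$lymphopenia_recovery_days)
  ramp <- c(neutrophils = 1, lymphocytes = 1, platelets = 1)
  rec <- isTRUE(case$recurrence)
  if (rec && !is.null(case$recurrence_day) && !is.na(case$recurrence_day)) {
    frac <- (day - (case$recurrence_day - config$ramp_onset_days)) /
      config$ramp_onset_days
    frac <- min(max(frac, 0), 1)  # flat before onset, plateau after detection
    ramp <- c(neutrophils = config$effect_neut^frac,
              lymphocytes = config$effect_lymph^frac,
              platelets = config$effect_plt^frac)
  }
  c(neutrophils = unname(baselines["neutrophils"] * ramp["neutrophils"]),
    lymphocytes = unname(baselines["lymphocytes"] * lymp_factor * ramp["lymphocytes"]),
    platelets = unname(baselines["platelets"] * ramp["platelets"]))
}

#' Generate a synthetic surveillance cohort
#'
#' Draws `n_patients` cases with Bernoulli recurrence labels, irregular
#' gamma-renewal visit schedules, clinical covariates, and per-visit blood
#' counts around the deterministic mean of [trajectory_value()] with
#' lognormal noise.  Recurrent cases are observed until 30 days after the
#' detection day (capped at the follow-up limit); non-recurrent cases until
#' a uniform censoring day.  Fully reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an `nlr_cohort`: list with `cases` and `visits` data frames plus
#'   `metadata` (the config and seed).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  recurrence <- runif(n) < config$recurrence_prob

  # Event day (recurrence detection, or the pseudo-event used for matched
  # censoring): Weibull truncated to (90, cap] by inverse CDF
  lo <- pweibull(90, config$recurrence_shape, config$recurrence_scale)
  hi <- pweibull(config$followup_cap_days, config$recurrence_shape,
                 config$recurrence_scale)
  u <- runif(n, lo, hi)
  event_day <- as.integer(pmin(pmax(round(
    qweibull(u, config$recurrence_shape, config$recurrence_scale)), 91),
    config$followup_cap_days))
  recurrence_day <- ifelse(recurrence, event_day, NA_integer_)

  age <- round(rnorm(n, config$age_mean, config$age_sd), 1)
  sex <- ifelse(runif(n) < config$male_frac, "male", "female")
  smoking <- ifelse(runif(n) < config$smoking_frac, "yes", "no")
  stage <- sample(STAGE_LEVELS, n, replace = TRUE, prob = config$stage_probs)

  censor <- if (config$censoring == "matched") {
    event_day
  } else {
    as.integer(round(runif(n, config$censor_min_days,
                           config$followup_cap_days)))
  }
  horizon <- ifelse(recurrence,
                    pmin(recurrence_day + 30L, config$followup_cap_days),
                    censor)

  shape <- (config$visit_interval_mean_days / config$visit_interval_sd_days)^2
  scale <- config$visit_interval_sd_days^2 / config$visit_interval_mean_days

  visit_list <- vector("list", n)
  for (i in seq_len(n)) {
    baselines <- exp(rnorm(3, config$baseline_log_means[VISIT_COLS[3:5]],
                           config$baseline_log_sds[VISIT_COLS[3:5]]))
    names(baselines) <- VISIT_COLS[3:5]
    day <- as.integer(round(runif(1, config$first_visit_range[1],
                                  config$first_visit_range[2])))
    days <- integer(0)
    while (day <= horizon[i]) {
      days <- c(days, day)
      day <- day + max(1L, as.integer(round(rgamma(1, shape = shape,
                                                   scale = scale))))
    }
    if (length(days) == 0) {
      visit_list[[i]] <- NULL
      next
    }
    case_i <- list(recurrence = recurrence[i], recurrence_day = recurrence_day[i])
    mu <- t(vapply(days, function(d)
      trajectory_value(case_i, d, config, baselines), numeric(3)))
    noise <- matrix(exp(rnorm(length(days) * 3, 0, config$noise_sd_log)),
                    ncol = 3)
    counts <- mu * noise
    counts[, "lymphocytes"] <- pmax(counts[, "lymphocytes"], 1)  # ratio floor
    visit_list[[i]] <- data.frame(
      patient_id = ids[i], day = days,
      neutrophils = counts[, "neutrophils"],
      lymphocytes = counts[, "lymphocytes"],
      platelets = counts[, "platelets"],
      stringsAsFactors = FALSE
    )
  }
  visits <- do.call(rbind, visit_list[!vapply(visit_list, is.null, logical(1))])
  if (is.null(visits)) visits <- empty_visit_table()
  rownames(visits) <- NULL

  last_visit <- tapply(visits$day, visits$patient_id, max)
  followup_end <- pmax(horizon, ifelse(ids %in% names(last_visit),
                                       last_visit[ids], 0L))

  cases <- data.frame(
    patient_id = ids, age = age, sex = sex, smoking = smoking, stage = stage,
    recurrence = recurrence, recurrence_day = recurrence_day,
    followup_end_day = as.integer(followup_end),
    stringsAsFactors = FALSE
  )

  new_cohort(cases, visits,
             metadata = list(generator = "nlrtrack synthetic cohort",
                             seed = config$seed,
                             config = unclass(config)))
}
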