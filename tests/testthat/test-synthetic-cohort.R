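test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(recurrence_prob = 1.4), "recurrence_prob")
  expect_error(sim_config(stage_probs = c(0.5, 0.5, 0.2, 0.1)), "stage_probs")
  expect_error(sim_config(effect_lymph = 0), "effect_lymph")
  expect_error(sim_config(effect_plt = 0.5), "effect_plt")
  expect_error(sim_config(lymphopenia_depth = 1), "lymphopenia_depth")
  expect_error(sim_config(visit_interval_mean_days = -2),
               "visit_interval_mean_days")
})

test_that("observed recurrence fraction matches the configured prevalence", {
  co <- generate_cohort(sim_config(n_patients = 10000, recurrence_prob = 0.265,
                                   seed = 20260928))
  frac <- mean(co$cases$recurrence)
  expect_lt(abs(frac - 0.265), 0.015)
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(sim_config(n_patients = 120, seed = 5))
  b <- generate_cohort(sim_config(n_patients = 120, seed = 5))
  c <- generate_cohort(sim_config(n_patients = 120, seed = 6))
  expect_identical(a$cases, b$cases)
  expect_identical(a$visits, b$visits)
  expect_false(identical(a$visits, c$visits))
})

test_that("generated cohorts satisfy all case and visit invariants", {
  for (s in 1:3) {
    co <- generate_cohort(sim_config(n_patients = 150, seed = s))
    expect_silent(validate_cohort(co))
    counts <- as.matrix(co$visits[, c("neutrophils", "lymphocytes",
                                      "platelets")])
    expect_true(all(is.finite(counts) & counts > 0))
    expect_true(all(co$visits$lymphocytes >= 1))
    rec <- co$cases[co$cases$recurrence, ]
    expect_true(all(rec$recurrence_day > 90))
    # visits strictly increasing per patient
    ord <- unlist(tapply(co$visits$day, co$visits$patient_id,
                         function(d) all(diff(d) > 0)))
    expect_true(all(ord))
  }
})

test_that("neutral effect sizes leave trajectories label-free", {
  co <- generate_cohort(sim_config(n_patients = 800, effect_neut = 1,
                                   effect_plt = 1, effect_lymph = 1,
                                   seed = 99))
  v <- compute_ratios(co$visits)
  per_case_nlr <- tapply(v$nlr, v$patient_id, mean)
  per_case_plr <- tapply(v$plr, v$patient_id, mean)
  lab <- setNames(co$cases$recurrence, co$cases$patient_id)[names(per_case_nlr)]
  expect_gt(suppressWarnings(
    ks.test(per_case_nlr[lab], per_case_nlr[!lab])$p.value), 0.01)
  expect_gt(suppressWarnings(
    ks.test(per_case_plr[lab], per_case_plr[!lab])$p.value), 0.01)
})

test_that("raising effect_plt does not lower mean PLR in the recurrence window", {
  window_plr <- function(effect) {
    co <- generate_cohort(sim_config(n_patients = 300, effect_plt = effect,
                                     seed = 77))
    v <- compute_ratios(co$visits)
    rec <- co$cases[co$cases$recurrence, ]
    vals <- c()
    for (i in seq_len(nrow(rec))) {
      rd <- rec$recurrence_day[i]
      w <- v[v$patient_id == rec$patient_id[i] &
               v$day >= rd - 90 & v$day <= rd + 30, ]
      vals <- c(vals, w$plr)
    }
    mean(vals)
  }
  m <- vapply(c(1, 1.5, 2), window_plr, numeric(1))
  expect_true(all(diff(m) >= 0))
})

test_that("noise-free trajectory means honour recovery and ramp limits", {
  cfg <- sim_config(effect_neut = 2, effect_plt = 1.8, effect_lymph = 0.5)
  base <- exp(cfg$baseline_log_means)

  # non-recurrent far out: lymphopenia factor has recovered to ~1
  nonrec <- list(recurrence = FALSE, recurrence_day = NA)
  far <- trajectory_value(nonrec, cfg$followup_cap_days, cfg)
  expect_equal(unname(far["lymphocytes"]), unname(base["lymphocytes"]),
               tolerance = 1e-4)

  rec <- list(recurrence = TRUE, recurrence_day = 500)
  # ramp onset: factor exactly 1 relative to the same-day baseline path
  at_onset <- trajectory_value(rec, 500 - cfg$ramp_onset_days, cfg)
  no_ramp <- trajectory_value(nonrec, 500 - cfg$ramp_onset_days, cfg)
  expect_equal(at_onset, no_ramp)
  # detection day: neutrophils exactly effect_neut x the ramp-free path
  at_det <- trajectory_value(rec, 500, cfg)
  no_ramp_det <- trajectory_value(nonrec, 500, cfg)
  expect_equal(unname(at_det["neutrophils"]),
               2 * unname(no_ramp_det["neutrophils"]))
  expect_equal(unname(at_det["lymphocytes"]),
               0.5 * unname(no_ramp_det["lymphocytes"]))
})
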