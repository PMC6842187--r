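# local helper mirroring the engine's eligibility lever
modify_config_for_test <- function(cfg, shift) {
  geo <- cfg$geography
  geo$eligible_mean <- geo$eligible_mean + shift
  model_config(geography = geo, n_iterations = cfg$n_iterations,
               master_seed = cfg$master_seed)
}

test_that("the simulation is bit-reproducible under a fixed master seed", {
  cfg <- small_config(n_iterations = 5)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$mrs_change, r2$mrs_change)
  # and one CE-plane point per iteration
  expect_equal(nrow(r1$per_iteration), 5)
  # extending the run never perturbs earlier iterations
  r3 <- run_simulation(cfg, n_iterations = 8)
  expect_equal(r3$per_iteration[1:5, !"iteration"],
               r1$per_iteration[, !"iteration"])
})

test_that("equal anchors produce no QALY effect and ambulance-only cost deltas", {
  flat <- treatment_effect_model(
    anchor_early = c(0.15, 0.2, 0.15, 0.16, 0.15, 0.06, 0.13),
    anchor_late = c(0.15, 0.2, 0.15, 0.16, 0.15, 0.06, 0.13)
  )
  cfg <- small_config(n_iterations = 5, outcome = flat)
  res <- run_simulation(cfg)
  expect_equal(res$per_iteration$delta_qaly, rep(0, 5))
  expect_equal(unname(res$mrs_change), rep(0, 7))
  # with identical outcomes and common random numbers, the whole cost
  # delta is the ambulance difference, which is also the whole year-1
  # budget impact; later-year budget impact vanishes
  expect_equal(res$per_iteration$delta_cost,
               res$per_iteration$budget_year1)
  expect_equal(res$per_iteration$budget_years2to5, rep(0, 5))
  # shorter transfers dominate, so ambulance costs fall
  expect_lt(mean(res$per_iteration$delta_cost), 0)
})

test_that("emptying the new-transfer class removes all worsened patients", {
  geo <- geography_params(n_affected = 2000, mean_evt_treated = 250,
                          n_shorter_transfer = 228, n_new_transfer = 0)
  cfg <- model_config(geography = geo, n_iterations = 3, master_seed = 7)
  set.seed(7)
  co <- generate_cohort(geo)
  expect_true(all(treatment_time_delta(co) >= 0))
  res <- run_simulation(cfg)
  expect_true(all(res$per_iteration$time_delta_mean > 0))
})

test_that("aggregates carry the headline statistics in Table shape", {
  cfg <- small_config(n_iterations = 8)
  res <- run_simulation(cfg)
  s <- res$summary
  expect_named(s$mrs_bands, c("independent_0_1", "dependent_dead_3_6"))
  expect_length(s$net_benefit, 3)
  expect_equal(vapply(s$net_benefit, `[[`, numeric(1), "wtp"),
               c(20000, 25000, 30000))
  # interval endpoints are the percentile bounds of the iteration draws
  expect_equal(s$delta_qaly$ci,
               unname(quantile(res$per_iteration$delta_qaly,
                               c(0.025, 0.975))))
  # ICER consistent with the mean ratio
  expect_equal(s$icer, s$delta_cost$mean / s$delta_qaly$mean)
  # CEAC evaluated over the configured grid
  expect_equal(res$ceac$wtp, cfg$economics$wtp_grid)
  expect_output(print(res), "Net benefit")
})

test_that("sensitivity variants move only their own levers", {
  cfg <- small_config(n_iterations = 4)
  suite <- run_sensitivity_suite(cfg)
  expect_equal(nrow(suite), 6)
  expect_equal(suite$delta_nb_25000[suite$variant == "base"], 0)
  # the ambulance tariff changes costs, never QALYs
  expect_equal(suite$delta_qaly[suite$variant == "ambulance_tariff"],
               suite$delta_qaly[suite$variant == "base"])
  expect_false(suite$delta_cost[suite$variant == "ambulance_tariff"] ==
                 suite$delta_cost[suite$variant == "base"])

  # higher eligibility treats more patients in expectation (same seeds)
  r_base <- run_simulation(cfg)
  r_up <- run_simulation(modify_config_for_test(cfg, +0.01))
  expect_gt(mean(r_up$per_iteration$n_treated),
            mean(r_base$per_iteration$n_treated))

  # younger cohorts survive longer: direct check on the survival model
  surv <- calibrate_survival_defaults()
  expect_gt(survival_quantile(surv, 0.5, 0, 65),
            survival_quantile(surv, 0.5, 0, 70))
})

test_that("the report writes the expected files and degrades gracefully", {
  cfg <- small_config(n_iterations = 4)
  res <- run_simulation(cfg)
  out <- withr::local_tempdir()
  paths <- write_report(res, out, plots = FALSE)
  expect_true(all(file.exists(paths)))
  expect_true(all(c("summary.csv", "ce_plane.csv", "mrs_change.csv",
                    "ceac.csv", "run_log.json") %in% basename(paths)))
  smry <- read.csv(file.path(out, "summary.csv"))
  # one row per reported statistic: 2 time stats + 7 mRS states + QALY +
  # cost + 3 net benefits + 2 budget rows
  expect_equal(nrow(smry), 16)
  plane <- read.csv(file.path(out, "ce_plane.csv"))
  expect_equal(nrow(plane), 4)

  # empty WTP grid: CEAC omitted, everything else written
  cfg2 <- small_config(
    n_iterations = 2,
    economics = economic_parameters(wtp_grid = numeric(0))
  )
  res2 <- run_simulation(cfg2)
  out2 <- withr::local_tempdir()
  paths2 <- write_report(res2, out2, plots = FALSE)
  expect_false("ceac.csv" %in% basename(paths2))
  expect_true("summary.csv" %in% basename(paths2))
})
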