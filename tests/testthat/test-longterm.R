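test_that("competing-risk probabilities rescale to sum to one", {
  rs <- rescale_competing_risks(0.20, 0.05)
  expect_equal(rs$death, 0.8)
  expect_equal(rs$det, 0.2)
  expect_equal(rescale_competing_risks(0.03, 0.01)$death, 0.75)
  expect_equal(rescale_competing_risks(0.03, 0.01)$det, 0.25)
  # single-risk case: any positive death probability alone maps to 1
  for (x in c(0.001, 0.4, 1)) {
    expect_equal(rescale_competing_risks(x, 0)$death, 1)
  }
  expect_error(rescale_competing_risks(0, 0), "positive")
  expect_error(rescale_competing_risks(1.2, 0.1), "\\[0, 1\\]")
})

test_that("survival calibration reproduces target medians analytically", {
  surv <- calibrate_survival_defaults()
  tab <- survival_calibration_table(surv)
  expect_equal(tab$achieved_median, tab$target_median, tolerance = 1e-8)
  # stochastically shorter survival for worse states
  expect_true(all(diff(tab$achieved_median) < 0))
  expect_error(calibrate_survival_defaults(c(8, 9, 7, 3, 2, 1)),
               "decreasing")
  expect_error(survival_model(annual_hazard = rep(0.1, 6),
                              mrs_hazard_ratio = c(2, 1, 1, 1, 1, 1)),
               "non-decreasing")
})

test_that("late-period hazard assembly multiplies its components exactly", {
  surv <- survival_model(annual_hazard = rep(0.1, 6), gompertz_a = 2e-5,
                         gompertz_b = 0.085,
                         mrs_hazard_ratio = c(1, 1.2, 1.5, 2, 3, 4),
                         late_mortality_reduction = 0.25)
  for (s in 0:5) {
    expect_equal(late_hazard(surv, s, 78),
                 2e-5 * exp(0.085 * 78) * c(1, 1.2, 1.5, 2, 3, 4)[s + 1] *
                   0.75)
  }
})

test_that("halving the hazard doubles median survival in the exponential limit", {
  # negligible background mortality isolates the single-piece hazard
  s1 <- survival_model(annual_hazard = rep(0.8, 6), gompertz_a = 1e-12)
  s2 <- survival_model(annual_hazard = rep(0.4, 6), gompertz_a = 1e-12)
  m1 <- survival_quantile(s1, 0.5, 3, 70) - 0.25
  m2 <- survival_quantile(s2, 0.5, 3, 70) - 0.25
  expect_equal(m2 / m1, 2, tolerance = 1e-8)
})

test_that("event histories respect the terminal and deterioration rules", {
  surv <- calibrate_survival_defaults()
  det <- deterioration_model()
  # 90-day death is recorded at the boundary with no deterioration
  h6 <- sample_event_history(rep(6L, 20), 70, surv, det)
  expect_equal(h6$death_time, rep(0.25, 20))
  expect_true(all(is.na(h6$deterioration_time)))

  set.seed(41)
  h <- sample_event_history(sample(0:5, 2e4, TRUE), runif(2e4, 40, 95),
                            surv, det)
  dt <- h$deterioration_time[!is.na(h$deterioration_time)]
  expect_true(all(dt > 0.25 & dt <= 5))
  # +2 increment capped at 5
  i <- !is.na(h$mrs_after_deterioration)
  expect_equal(h$mrs_after_deterioration[i],
               pmin(h$mrs90[i] + 2L, 5L))
  # death always after deterioration
  expect_true(all(h$death_time[i] > h$deterioration_time[i]))
  # mRS 4-5 carry no separate deterioration event by default
  expect_true(all(h$mrs90[i] <= 3))
})

test_that("death is certain by the age-100 horizon", {
  surv <- calibrate_survival_defaults()
  det <- deterioration_model()
  set.seed(42)
  age <- runif(5000, 30, 99)
  h <- sample_event_history(sample(0:6, 5000, TRUE), age, surv, det)
  expect_true(all(is.finite(h$death_time)))
  expect_true(all(h$death_time <= 100 - age + 1e-9))
})

test_that("deterioration forced on maps states as configured", {
  surv <- calibrate_survival_defaults()
  det1 <- deterioration_model(rep(1, 4))  # certain deterioration, month 1
  h <- sample_event_history(rep(2L, 100), 60, surv, det1,
                            u_event = rep(0.5, 100),
                            u_type = rep(0.999, 100))
  expect_true(all(!is.na(h$deterioration_time)))
  expect_equal(h$mrs_after_deterioration, rep(4L, 100))
})

test_that("sampled death times match the configured survival function", {
  surv <- calibrate_survival_defaults()
  det0 <- deterioration_model(rep(0, 4))  # death only
  set.seed(43)
  n <- 1e5
  for (s in c(0L, 5L)) {
    h <- sample_event_history(rep(s, n), 70, surv, det0)
    # the analytic median splits the sample evenly (binomial 4-sigma band)
    target <- survival_quantile(surv, 0.5, s, 70)
    expect_lt(abs(mean(h$death_time <= target) - 0.5), 4 * sqrt(0.25 / n))
    # KS agreement with the independent month-product + integration oracle,
    # evaluated on a dense grid including the month boundaries
    cdf <- function(t) event_time_cdf_oracle(
      t, surv$annual_hazard[s + 1], surv$mrs_hazard_ratio[s + 1], 70, surv)
    grid <- sort(c(0.25 + (0:57) / 12, seq(0.26, 30, length.out = 1500)))
    expect_lt(ks_distance(h$death_time, cdf, grid), 1.95 / sqrt(n) + 0.002)
  }
})

test_that("monotonicity: worse 90-day states die sooner on average", {
  surv <- calibrate_survival_defaults()
  det <- deterioration_model()
  set.seed(44)
  med <- vapply(0:5, function(s) {
    median(sample_event_history(rep(s, 2e4), 70, surv, det)$death_time)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
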