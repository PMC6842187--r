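test_that("utility marginals have the published analytic means", {
  ec <- economic_parameters()
  means <- ec$utility_alpha / (ec$utility_alpha + ec$utility_beta)
  expect_equal(round(means, 2), c(0.95, 0.93, 0.83, 0.62, 0.42, 0.11))
  # Monte Carlo mean of the mRS 0 utility
  set.seed(51)
  u0 <- replicate(1e4, draw_parameters(ec)$utilities[1])
  expect_lt(abs(mean(u0) - 0.95), 0.003)
})

test_that("every draw preserves the utility ordering across states", {
  ec <- economic_parameters()
  set.seed(52)
  for (i in 1:2000) {
    d <- draw_parameters(ec)
    expect_true(all(diff(d$utilities) <= 0))
    expect_true(all(d$utilities >= 0 & d$utilities <= 1))
    expect_true(all(d$cost_year1 >= 0) && all(d$cost_subsequent >= 0))
  }
  # the gaussian copula option also never crosses after sorting
  ecg <- economic_parameters(copula = "gaussian")
  for (i in 1:500) {
    expect_true(all(diff(draw_parameters(ecg)$utilities) <= 0))
  }
})

test_that("a forced median uniform returns each beta median", {
  ec <- economic_parameters(cost_stochastic = FALSE)
  d <- draw_parameters(ec, u_utility = 0.5)
  med <- qbeta(0.5, ec$utility_alpha, ec$utility_beta)
  expect_equal(d$utilities, c(sort(med, decreasing = TRUE), 0))
  expect_equal(d$cost_year1, ec$cost_year1)
})

test_that("EVT cost draws have the configured gamma mean", {
  ec <- economic_parameters()
  set.seed(53)
  x <- rgamma(2e5, shape = ec$evt_cost_shape, scale = ec$evt_cost_scale)
  expect_equal(mean(x), 554.86 * 16.42, tolerance = 0.005)
})

test_that("QALY accumulation matches closed forms", {
  ec <- economic_parameters()
  u <- c(0.95, 0.93, 0.83, 0.62, 0.42, 0.11, 0)
  hist1 <- data.table::data.table(
    mrs90 = c(6L, 0L, 0L),
    deterioration_time = NA_real_,
    mrs_after_deterioration = NA_integer_,
    death_time = c(0.25, 1, 2)
  )
  # death at 90 days: zero QALYs
  expect_equal(accumulate_qalys(hist1, u, 0.035)[1], 0)
  # one year at utility 0.95 undiscounted
  expect_equal(accumulate_qalys(hist1, u, 0)[2], 0.95)
  # two years at constant utility: u * (1 + 1/(1+r))
  r <- 0.035
  expect_equal(accumulate_qalys(hist1, u, r)[3], 0.95 * (1 + 1 / (1 + r)))
  # discounting off: utility-weighted lifespan exactly, with a mid-life
  # deterioration switching the state
  hist2 <- data.table::data.table(
    mrs90 = 1L, deterioration_time = 2.5, mrs_after_deterioration = 3L,
    death_time = 4.75
  )
  expect_equal(accumulate_qalys(hist2, u, 0), 0.93 * 2.5 + 0.62 * 2.25)
})

test_that("cost accumulation matches the published tariffs", {
  ec <- economic_parameters(cost_stochastic = FALSE)
  draw <- draw_parameters(ec)
  draw$evt_cost <- 9116
  path <- data.table::data.table(
    onset_to_evt = c(200, 200, 200), required_transfer = c(TRUE, TRUE, FALSE),
    ambulance_minutes = c(20, 0, 0)
  )
  hist <- data.table::data.table(
    mrs90 = c(6L, 3L, 3L),
    deterioration_time = NA_real_, mrs_after_deterioration = NA_integer_,
    death_time = c(0.25, 2, 2)
  )
  cost <- accumulate_costs(hist, path, draw, ec, 0)
  # dead at 90 days: EVT + ambulance only (20 min at 6.86)
  expect_equal(cost[1], 9116 + 20 * 6.86)
  # mRS 3 survivor to exactly year 2, r = 0: year-1 + one subsequent year
  expect_equal(cost[2], 9116 + 35771 + 12291)
  expect_equal(cost[3], 9116 + 35771 + 12291)
  # tariff mode replaces per-minute costing with a per-mission charge
  ect <- economic_parameters(cost_stochastic = FALSE,
                             ambulance_mode = "tariff")
  cost_t <- accumulate_costs(hist, path, draw, ect, 0)
  expect_equal(cost_t[1] - cost[1], 234 - 20 * 6.86)
  expect_equal(cost_t[2] - cost[2], 234)    # zero-minute mission still billed
  expect_equal(cost_t[3], cost[3])          # no transfer, no tariff
})

test_that("net benefit values QALY gains and losses symmetrically", {
  expect_equal(net_benefit(0, 0, 25000), 0)
  # consistency with the headline arithmetic: wtp * dQ - dC
  expect_equal(net_benefit(213, -2870000, 20000), 7130000)
  # cost-saving with QALY loss still enters the valuation
  expect_equal(net_benefit(-1, -50000, 20000), 30000)
  # linear in wtp
  dq <- 3.2; dc <- -1e4
  w <- c(0, 1e4, 2e4, 3e4)
  expect_equal(diff(net_benefit(dq, dc, w)), rep(dq * 1e4, 3))
})

test_that("the acceptability curve is a correct step function", {
  # single draw: steps from 0 to 1 exactly at its ICER
  cc <- ceac(1, 25000, wtp_grid = c(0, 24999, 25000, 25001, 50000))
  expect_equal(cc$probability, c(0, 0, 0, 1, 1))
  # dominant quadrant: probability 1 everywhere
  cc <- ceac(c(1, 2), c(-100, -50), wtp_grid = c(0, 10000, 50000))
  expect_equal(cc$probability, rep(1, 3))
  # at wtp = 0 the curve equals the fraction of cost-saving draws
  set.seed(54)
  dq <- rnorm(500); dc <- rnorm(500, 0, 100)
  expect_equal(ceac(dq, dc, 0)$probability, mean(dc < 0))
  # non-decreasing in wtp when all QALY gains are non-negative
  dq <- abs(dq)
  expect_true(all(diff(ceac(dq, dc)$probability) >= 0))
  expect_error(ceac(numeric(0), numeric(0)), "at least one")
})

test_that("budget impact isolates year 1 and discounted years 2-5", {
  ec <- economic_parameters(cost_stochastic = FALSE)
  draw <- draw_parameters(ec)
  path <- data.table::data.table(onset_to_evt = 200, required_transfer = FALSE,
                                 ambulance_minutes = 0)
  mk <- function(death) data.table::data.table(
    mrs90 = 2L, deterioration_time = NA_real_,
    mrs_after_deterioration = NA_integer_, death_time = death)
  # identical scenarios: zero impact
  cb <- cost_components(mk(6), path, draw, ec, 0.035)
  expect_equal(unlist(budget_impact(cb, cb)), c(year1 = 0, years2to5 = 0))
  # no survival past year 1: years 2-5 contribute nothing
  c1 <- cost_components(mk(1), path, draw, ec, 0.035)
  expect_equal(c1$care_years2to5, 0)
  # discounting off: years 2-5 equal the undiscounted annual sum
  c0 <- cost_components(mk(6), path, draw, ec, 0)
  expect_equal(c0$care_years2to5, 4 * ec$cost_subsequent[3])
  expect_equal(c0$care_year1, ec$cost_year1[3])
})
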