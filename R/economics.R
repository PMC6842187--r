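#' Economic parameters
#'
#' Cost and utility inputs of the lifetime cost-utility analysis, with the
#' published uncertainty distributions: beta-distributed utilities per mRS
#' state (means 0.95, 0.93, 0.83, 0.62, 0.42, 0.11; mRS 6 fixed at 0),
#' gamma-distributed EVT procedure cost (shape 554.86, scale 16.42; mean
#' about 9,116 GBP), Category A ambulance cost of 6.86 GBP per minute
#' (alternatively a 234 GBP per-mission tariff), and first-year /
#' subsequent-year care costs per mRS state. Care-cost uncertainty uses
#' the SE-equals-mean convention, giving gamma marginals with shape 1.
#'
#' @param utility_alpha,utility_beta beta shape parameters for mRS 0..5.
#' @param cost_year1 first-year care cost per mRS 0..6, GBP.
#' @param cost_subsequent annual care cost thereafter per mRS 0..6, GBP.
#' @param evt_cost_shape,evt_cost_scale gamma parameters of the EVT cost.
#' @param ambulance_cost_per_min GBP per minute of secondary transfer.
#' @param ambulance_tariff GBP per secondary-transfer mission (sensitivity
#'   analysis alternative).
#' @param ambulance_mode `"per_minute"` or `"tariff"`.
#' @param cost_stochastic draw care costs per iteration (`TRUE`) or hold
#'   them at their means.
#' @param copula `"comonotonic"` (one shared uniform per parameter family)
#'   or `"gaussian"` (one-factor Gaussian copula); either way utilities
#'   are sorted so a worse state never has higher utility within a draw.
#' @param copula_correlation correlation of the Gaussian copula factor.
#' @param discount_rate annual discount rate applied to costs and QALYs
#'   from year 2 (default 0.035).
#' @param wtp_grid willingness-to-pay thresholds (GBP/QALY) for the CEAC.
#' @return an object of class `economic_parameters`.
#' @export
economic_parameters <- function(
    utility_alpha = c(48.4, 128.04, 222.24, 173.70, 173.15, 6.07),
    utility_beta = c(2.55, 9.64, 45.52, 106.46, 239.11, 49.12),
    cost_year1 = c(6620, 11196, 18929, 35771, 60118, 60458, 0),
    cost_subsequent = c(2122, 2836, 4722, 12291, 30750, 28853, 0),
    evt_cost_shape = 554.86, evt_cost_scale = 16.42,
    ambulance_cost_per_min = 6.86,
    ambulance_tariff = 234,
    ambulance_mode = c("per_minute", "tariff"),
    cost_stochastic = TRUE,
    copula = c("comonotonic", "gaussian"),
    copula_correlation = 0.9,
    discount_rate = 0.035,
    wtp_grid = seq(0, 50000, by = 1000)) {
  ambulance_mode <- match.arg(ambulance_mode)
  copula <- match.arg(copula)
  stopifnot(length(utility_alpha) == 6L, length(utility_beta) == 6L,
            all(utility_alpha > 0), all(utility_beta > 0),
            length(cost_year1) == 7L, length(cost_subsequent) == 7L,
            all(cost_year1 >= 0), all(cost_subsequent >= 0),
            cost_year1[7] == 0, cost_subsequent[7] == 0,
            evt_cost_shape > 0, evt_cost_scale > 0,
            ambulance_cost_per_min >= 0, ambulance_tariff >= 0,
            discount_rate >= 0,
            copula_correlation >= 0, copula_correlation <= 1)
  means <- utility_alpha / (utility_alpha + utility_beta)
  if (any(diff(means) > 1e-9))
    stop("mean utilities must be non-increasing in mRS")
  structure(
    list(utility_alpha = utility_alpha, utility_beta = utility_beta,
         utility_mean = means,
         cost_year1 = cost_year1, cost_subsequent = cost_subsequent,
         evt_cost_shape = evt_cost_shape, evt_cost_scale = evt_cost_scale,
         ambulance_cost_per_min = ambulance_cost_per_min,
         ambulance_tariff = ambulance_tariff,
         ambulance_mode = ambulance_mode,
         cost_stochastic = cost_stochastic,
         copula = copula, copula_correlation = copula_correlation,
         discount_rate = discount_rate, wtp_grid = wtp_grid),
    class = "economic_parameters"
  )
}

# family uniforms under the chosen copula: comonotonic reuses one uniform
# across the k marginals; gaussian uses a one-factor latent structure
family_uniforms <- function(k, params, u_shared = NULL) {
  u0 <- u_shared %||% runif(1)
  if (params$copula == "comonotonic") return(rep(u0, k))
  rho <- params$copula_correlation
  z0 <- qnorm(u0)
  pnorm(sqrt(rho) * z0 + sqrt(1 - rho) * rnorm(k))
}

#' Draw one set of correlated economic parameters
#'
#' One probabilistic-sensitivity-analysis realisation: utilities per mRS
#' state from their beta marginals, care costs from their gamma marginals,
#' and the EVT cost from its gamma distribution. Within a family the
#' marginals share copula uniforms, and utilities are sorted in
#' non-increasing mRS order afterwards, so a simulation run never assigns
#' a worse state a higher utility (e.g. u(mRS 3) never exceeds u(mRS 2)).
#'
#' @param params an [economic_parameters()] object.
#' @param u_utility,u_cost1,u_cost2 optional shared family uniforms for
#'   reproducible draws; drawn internally when `NULL`.
#' @return a list of class `parameter_draw` with `utilities` (length 7,
#'   mRS 6 = 0), `cost_year1`, `cost_subsequent` (length 7), `evt_cost`.
#' @export
draw_parameters <- function(params, u_utility = NULL, u_cost1 = NULL,
                            u_cost2 = NULL) {
  stopifnot(inherits(params, "economic_parameters"))
  uu <- family_uniforms(6, params, u_utility)
  util <- qbeta(uu, params$utility_alpha, params$utility_beta)
  util <- sort(util, decreasing = TRUE)          # enforce state ordering
  if (params$cost_stochastic) {
    # SE = mean => gamma with shape 1 and scale equal to the mean
    uc1 <- family_uniforms(6, params, u_cost1)
    uc2 <- family_uniforms(6, params, u_cost2)
    c1 <- c(qgamma(uc1, shape = 1, scale = params$cost_year1[1:6]), 0)
    c2 <- c(qgamma(uc2, shape = 1, scale = params$cost_subsequent[1:6]), 0)
  } else {
    c1 <- params$cost_year1
    c2 <- params$cost_subsequent
  }
  structure(
    list(utilities = c(util, 0), cost_year1 = c1, cost_subsequent = c2,
         evt_cost = rgamma(1, shape = params$evt_cost_shape,
                           scale = params$evt_cost_scale)),
    class = "parameter_draw"
  )
}

# split each lived trajectory into (start, end, state) pieces:
# piece 1 runs at mrs90 until deterioration (or death), piece 2 at the
# post-deterioration state until death
trajectory_pieces <- function(history) {
  has_det <- !is.na(history$deterioration_time)
  end1 <- ifelse(has_det,
                 pmin(history$deterioration_time, history$death_time),
                 history$death_time)
  list(has_det = has_det, end1 = end1)
}

#' Accumulate discounted lifetime QALYs
#'
#' Integrates the utility of the occupied mRS state over each lived
#' interval (the first 90 days accrue at the 90-day state; the state
#' switches at deterioration), with discrete annual discounting: year 1
#' undiscounted, year k weighted by (1+r)^-(k-1), partial years prorated.
#'
#' @param history event histories from [sample_event_history()].
#' @param utilities length-7 utility vector of a [draw_parameters()] draw.
#' @param discount_rate annual discount rate.
#' @return numeric vector of discounted QALYs per patient.
#' @export
accumulate_qalys <- function(history, utilities, discount_rate = 0.035) {
  stopifnot(length(utilities) == 7L)
  tp <- trajectory_pieces(history)
  q <- utilities[history$mrs90 + 1L] *
    discounted_interval(0, tp$end1, discount_rate)
  if (any(tp$has_det)) {
    i <- tp$has_det
    q[i] <- q[i] + utilities[history$mrs_after_deterioration[i] + 1L] *
      discounted_interval(history$deterioration_time[i],
                          history$death_time[i], discount_rate)
  }
  q
}

#' Lifetime cost components per patient
#'
#' Decomposes each patient's discounted lifetime cost into the EVT
#' procedure, the secondary-transfer ambulance journey, first-year care,
#' care over years 2--5 (discounted), and care beyond year 5 (discounted).
#' First-year care is charged at the first-year rate of the occupied state
#' and subsequent years at the annual-thereafter rate, with the state
#' switching at deterioration and partial years prorated.
#'
#' @param history event histories from [sample_event_history()].
#' @param pathway the matching scenario's [compute_pathway()] table.
#' @param draw a [draw_parameters()] draw.
#' @param params an [economic_parameters()] object.
#' @param discount_rate annual discount rate.
#' @return a `data.table` with columns `evt`, `ambulance`, `care_year1`,
#'   `care_years2to5`, `care_later`.
#' @export
cost_components <- function(history, pathway, draw, params,
                            discount_rate = 0.035) {
  stopifnot(nrow(history) == nrow(pathway))
  tp <- trajectory_pieces(history)
  r <- discount_rate

  piece_care <- function(a, b, state) {
    # care over [a, b) in `state`: first-year rate inside [0,1),
    # thereafter rate beyond, discounted; windowed pieces for reporting
    y1 <- draw$cost_year1[state + 1L] *
      discounted_interval(pmin(a, 1), pmin(b, 1), r)
    y2to5 <- draw$cost_subsequent[state + 1L] *
      discounted_interval(clamp(a, 1, 5), clamp(b, 1, 5), r)
    later <- draw$cost_subsequent[state + 1L] *
      discounted_interval(pmax(a, 5), pmax(b, 5), r)
    list(y1 = y1, y2to5 = y2to5, later = later)
  }

  p1 <- piece_care(rep(0, nrow(history)), tp$end1, history$mrs90)
  y1 <- p1$y1; y2to5 <- p1$y2to5; later <- p1$later
  if (any(tp$has_det)) {
    i <- tp$has_det
    p2 <- piece_care(history$deterioration_time[i], history$death_time[i],
                     history$mrs_after_deterioration[i])
    y1[i] <- y1[i] + p2$y1
    y2to5[i] <- y2to5[i] + p2$y2to5
    later[i] <- later[i] + p2$later
  }

  amb <- if (params$ambulance_mode == "per_minute") {
    params$ambulance_cost_per_min * pathway$ambulance_minutes
  } else {
    params$ambulance_tariff * as.numeric(pathway$required_transfer)
  }
  data.table::data.table(
    evt = rep(draw$evt_cost, nrow(history)),
    ambulance = amb,
    care_year1 = y1,
    care_years2to5 = y2to5,
    care_later = later
  )
}

#' Accumulate discounted lifetime costs
#'
#' Total per-patient cost: EVT procedure + ambulance transfer + lifetime
#' care (see [cost_components()]).
#'
#' @inheritParams cost_components
#' @return numeric vector of discounted costs in GBP per patient.
#' @export
accumulate_costs <- function(history, pathway, draw, params,
                             discount_rate = 0.035) {
  comp <- cost_components(history, pathway, draw, params, discount_rate)
  comp$evt + comp$ambulance + comp$care_year1 + comp$care_years2to5 +
    comp$care_later
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`. QALY losses are valued at the same
#' threshold as gains: a cost-saving run with a QALY loss still has its
#' lost QALYs monetised and netted against the savings.
#'
#' @param delta_qaly incremental QALYs (vector).
#' @param delta_cost incremental cost in GBP (vector).
#' @param wtp willingness to pay per QALY, GBP.
#' @return net monetary benefit in GBP.
#' @export
net_benefit <- function(delta_qaly, delta_cost, wtp) {
  wtp * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of simulation draws
#' with positive net monetary benefit.
#'
#' @param delta_qaly,delta_cost per-iteration incremental QALYs and costs.
#' @param wtp_grid thresholds in GBP per QALY.
#' @return a data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(delta_qaly, delta_cost, wtp_grid = seq(0, 50000, 1000)) {
  if (length(delta_qaly) == 0L) stop("at least one draw is required")
  stopifnot(length(delta_qaly) == length(delta_cost))
  prob <- vapply(wtp_grid, function(w)
    mean(net_benefit(delta_qaly, delta_cost, w) > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Budget impact
#'
#' Cash-flow consequence of the reconfiguration: the year-1 component is
#' the mean marginal (EVT + ambulance + first-year care) cost, and the
#' years-2-to-5 component the mean marginal discounted care cost over
#' years 2--5 only, truncated at death.
#'
#' @param components_baseline,components_reconfig per-patient
#'   [cost_components()] tables for the two scenarios (matched rows), or
#'   per-iteration sums thereof.
#' @return a list with `year1` and `years2to5` (GBP; negative = saving).
#' @export
budget_impact <- function(components_baseline, components_reconfig) {
  d <- function(col) mean(components_reconfig[[col]] -
                            components_baseline[[col]])
  list(
    year1 = d("evt") + d("ambulance") + d("care_year1"),
    years2to5 = d("care_years2to5")
  )
}
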