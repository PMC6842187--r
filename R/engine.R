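#' Run the full discrete event simulation
#'
#' Orchestrates the two-scenario simulation: per iteration it draws the
#' eligible fraction and the correlated economic parameters once,
#' regenerates the affected cohort (geography uncertainty), simulates
#' every EVT-eligible early presenter under the 24-centre baseline and the
#' 30-centre reconfiguration with common random numbers (shared uniforms
#' for 90-day outcome and post-90-day event sampling), accumulates
#' discounted lifetime QALYs and costs, and sums marginal effects across
#' patients to one point on the cost-effectiveness plane. Results are
#' aggregated across iterations into means with 95% percentile intervals.
#'
#' @param config a [model_config()] object.
#' @param n_iterations optional override of the configured iteration count.
#' @param seed optional override of the configured master seed.
#' @return an object of class `evtdes_results`: list with `per_iteration`
#'   (a `data.table`, one row per iteration), `mrs_change` (mean per-state
#'   count deltas), `summary` (headline statistics), `ceac`, `config`.
#' @export
run_simulation <- function(config, n_iterations = NULL, seed = NULL) {
  validate_config(config)
  n_iter <- n_iterations %||% config$n_iterations
  seed <- seed %||% config$master_seed
  stopifnot(n_iter >= 1)

  sampler <- onset_sampler(config$onset_quartiles, config$onset_support)
  surv <- calibrate_survival_defaults(config$survival_medians,
                                      age = config$survival_age)
  det <- config$deterioration
  geo <- config$geography
  econ <- config$economics
  r <- econ$discount_rate

  # seed hierarchy: master seed fixes the per-iteration seed stream, so
  # extending the run never perturbs earlier iterations
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)

  rows <- vector("list", n_iter)
  delta_counts <- matrix(0, n_iter, 7)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    it <- simulate_iteration(geo, sampler, config$pathway, config$outcome,
                             surv, det, econ, r)
    rows[[i]] <- it$row
    delta_counts[i, ] <- it$delta_counts
  }
  per_iter <- data.table::rbindlist(rows)
  per_iter[, iteration := seq_len(n_iter)]

  mrs_change <- setNames(colMeans(delta_counts), paste0("mrs", 0:6))
  res <- structure(
    list(per_iteration = per_iter,
         mrs_change = mrs_change,
         summary = summarise_results(per_iter, mrs_change, econ),
         ceac = ceac(per_iter$delta_qaly, per_iter$delta_cost,
                     econ$wtp_grid),
         config = config, seed = seed, n_iterations = n_iter),
    class = "evtdes_results"
  )
  res
}

# one PSA iteration: returns a one-row data.table of aggregates plus the
# mRS count-delta vector
simulate_iteration <- function(geo, sampler, constants, outcome_model,
                               surv, det, econ, r) {
  frac <- draw_eligible_fraction(1, geo$eligible_mean, geo$eligible_sd)
  draw <- draw_parameters(econ)
  cohort <- generate_cohort(geo, sampler, eligible_fraction = frac)
  el <- cohort[cohort$eligible_evt, ]
  n_el <- nrow(el)
  if (n_el == 0L) stop("no eligible patients generated; check geography")

  path_b <- compute_pathway(el, "baseline", constants)
  path_r <- compute_pathway(el, "reconfigured", constants)

  # common random numbers: shared uniforms per patient across scenarios
  u_mrs <- runif(n_el)
  u_event <- runif(n_el); u_type <- runif(n_el); u_death <- runif(n_el)

  mrs_b <- sample_mrs90(path_b$onset_to_evt, outcome_model, u_mrs)
  mrs_r <- sample_mrs90(path_r$onset_to_evt, outcome_model, u_mrs)
  hist_b <- sample_event_history(mrs_b, el$age, surv, det,
                                 u_event, u_type, u_death)
  hist_r <- sample_event_history(mrs_r, el$age, surv, det,
                                 u_event, u_type, u_death)

  q_b <- accumulate_qalys(hist_b, draw$utilities, r)
  q_r <- accumulate_qalys(hist_r, draw$utilities, r)
  comp_b <- cost_components(hist_b, path_b, draw, econ, r)
  comp_r <- cost_components(hist_r, path_r, draw, econ, r)
  cost_b <- comp_b$evt + comp_b$ambulance + comp_b$care_year1 +
    comp_b$care_years2to5 + comp_b$care_later
  cost_r <- comp_r$evt + comp_r$ambulance + comp_r$care_year1 +
    comp_r$care_years2to5 + comp_r$care_later

  bi <- budget_impact(comp_b, comp_r)
  dt_treat <- path_b$onset_to_evt - path_r$onset_to_evt

  row <- data.table::data.table(
    n_treated = n_el,
    eligible_fraction = frac,
    delta_qaly = sum(q_r) - sum(q_b),
    delta_cost = sum(cost_r) - sum(cost_b),
    budget_year1 = bi$year1 * n_el,
    budget_years2to5 = bi$years2to5 * n_el,
    time_delta_mean = mean(dt_treat),
    time_delta_sd = stats::sd(dt_treat),
    tt_baseline_median = median(path_b$onset_to_evt),
    tt_baseline_q25 = unname(quantile(path_b$onset_to_evt, 0.25)),
    tt_baseline_q75 = unname(quantile(path_b$onset_to_evt, 0.75)),
    tt_reconfig_median = median(path_r$onset_to_evt),
    tt_reconfig_q25 = unname(quantile(path_r$onset_to_evt, 0.25)),
    tt_reconfig_q75 = unname(quantile(path_r$onset_to_evt, 0.75))
  )
  list(row = row,
       delta_counts = tabulate(mrs_r + 1L, 7L) - tabulate(mrs_b + 1L, 7L))
}

percentile_ci <- function(x) unname(quantile(x, c(0.025, 0.975)))

summarise_results <- function(per_iter, mrs_change, econ) {
  dq <- per_iter$delta_qaly
  dc <- per_iter$delta_cost
  nb <- lapply(c(20000, 25000, 30000), function(w) {
    v <- net_benefit(dq, dc, w)
    list(wtp = w, mean = mean(v), ci = percentile_ci(v))
  })
  mean_dq <- mean(dq)
  list(
    n_iterations = nrow(per_iter),
    mean_n_treated = mean(per_iter$n_treated),
    sd_n_treated = stats::sd(per_iter$n_treated),
    delta_qaly = list(mean = mean_dq, ci = percentile_ci(dq)),
    delta_cost = list(mean = mean(dc), ci = percentile_ci(dc)),
    icer = if (abs(mean_dq) < 1e-9) NA_real_ else mean(dc) / mean_dq,
    icer_undefined = abs(mean_dq) < 1e-9,
    net_benefit = nb,
    budget_year1 = list(mean = mean(per_iter$budget_year1),
                        ci = percentile_ci(per_iter$budget_year1)),
    budget_years2to5 = list(mean = mean(per_iter$budget_years2to5),
                            ci = percentile_ci(per_iter$budget_years2to5)),
    mrs_change = mrs_change,
    mrs_bands = mrs_band_changes(mrs_change),
    time_delta = list(mean = mean(per_iter$time_delta_mean),
                      sd = mean(per_iter$time_delta_sd)),
    tt_baseline = c(median = mean(per_iter$tt_baseline_median),
                    q25 = mean(per_iter$tt_baseline_q25),
                    q75 = mean(per_iter$tt_baseline_q75)),
    tt_reconfig = c(median = mean(per_iter$tt_reconfig_median),
                    q25 = mean(per_iter$tt_reconfig_q25),
                    q75 = mean(per_iter$tt_reconfig_q75))
  )
}

#' @export
print.evtdes_results <- function(x, ...) {
  s <- x$summary
  fmt_ci <- function(v, d = 0) sprintf("(95%% CI %s to %s)",
                                       format(round(v[1], d), big.mark = ","),
                                       format(round(v[2], d), big.mark = ","))
  cat("EVT service reconfiguration DES:", s$n_iterations, "iterations\n")
  cat(sprintf("  Mean treated patients/year: %.0f (SD %.1f)\n",
              s$mean_n_treated, s$sd_n_treated))
  cat(sprintf("  Mean time-to-treatment reduction: %.1f min (SD %.1f)\n",
              s$time_delta$mean, s$time_delta$sd))
  cat(sprintf("  Marginal QALYs: %.0f %s\n", s$delta_qaly$mean,
              fmt_ci(s$delta_qaly$ci)))
  cat(sprintf("  Marginal cost: £%s %s\n",
              format(round(s$delta_cost$mean), big.mark = ","),
              fmt_ci(s$delta_cost$ci)))
  for (nb in s$net_benefit)
    cat(sprintf("  Net benefit at £%s/QALY: £%s %s\n",
                format(nb$wtp, big.mark = ","),
                format(round(nb$mean), big.mark = ","), fmt_ci(nb$ci)))
  cat(sprintf("  Budget impact year 1: £%s; years 2-5: £%s\n",
              format(round(s$budget_year1$mean), big.mark = ","),
              format(round(s$budget_years2to5$mean), big.mark = ",")))
  cat("  Population mRS change (reconfig - baseline):\n")
  print(round(x$mrs_change, 1))
  invisible(x)
}

#' One-way sensitivity analyses
#'
#' Re-runs the simulation under the three published one-way variants --
#' ambulance mission tariff (234 GBP) replacing per-minute costing, the
#' early-LAO eligible proportion shifted by +/- 1 percentage point, and
#' mean age at stroke shifted by +/- 5 years -- each with the same master
#' seed as the base case, reporting the change in net monetary benefit at
#' 25,000 GBP per QALY.
#'
#' @param config a [model_config()] object.
#' @param n_iterations optional iteration override applied to every run.
#' @return a data.frame with one row per run (base + 5 variants): mean
#'   incremental QALYs and cost, net benefit at 25,000 GBP/QALY and its
#'   change from base.
#' @export
run_sensitivity_suite <- function(config, n_iterations = NULL) {
  variants <- list(
    base = config,
    ambulance_tariff = modify_config(config, ambulance_mode = "tariff"),
    eligibility_up = modify_config(config, eligible_shift = +0.01),
    eligibility_down = modify_config(config, eligible_shift = -0.01),
    age_minus5 = modify_config(config, age_shift = -5),
    age_plus5 = modify_config(config, age_shift = +5)
  )
  rows <- lapply(names(variants), function(nm) {
    res <- run_simulation(variants[[nm]], n_iterations = n_iterations)
    s <- res$summary
    nb25 <- s$net_benefit[[2]]
    data.frame(variant = nm, delta_qaly = s$delta_qaly$mean,
               delta_cost = s$delta_cost$mean, nb_25000 = nb25$mean)
  })
  out <- do.call(rbind, rows)
  out$delta_nb_25000 <- out$nb_25000 - out$nb_25000[out$variant == "base"]
  out
}

# rebuild a config with one sensitivity knob turned; age shifts move the
# cohort mean age only (age enters outcomes solely through post-90-day
# survival; the survival calibration reference stays at 70)
modify_config <- function(config, ambulance_mode = NULL,
                          eligible_shift = 0, age_shift = 0) {
  geo <- config$geography
  econ <- config$economics
  if (!is.null(ambulance_mode)) econ$ambulance_mode <- ambulance_mode
  geo$eligible_mean <- geo$eligible_mean + eligible_shift
  geo$mean_age <- geo$mean_age + age_shift
  model_config(
    geography = geo,
    onset_quartiles = config$onset_quartiles,
    onset_support = config$onset_support,
    pathway = config$pathway,
    outcome = config$outcome,
    survival_medians = config$survival_medians,
    survival_age = config$survival_age,
    deterioration = config$deterioration,
    economics = econ,
    n_iterations = config$n_iterations,
    master_seed = config$master_seed
  )
}
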