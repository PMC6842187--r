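# shared fixtures: a scaled-down geography for engine tests and a
# hand-built cohort constructor for pathway/outcome unit tests

small_geography <- function(...) {
  geography_params(n_affected = 2000, mean_evt_treated = 250,
                   n_shorter_transfer = 228, n_new_transfer = 22, ...)
}

small_config <- function(n_iterations = 10, master_seed = 101, ...) {
  model_config(geography = small_geography(), n_iterations = n_iterations,
               master_seed = master_seed, ...)
}

make_cohort <- function(onset, transfer_class, t_base = 0, t_reco = 0,
                        age = 70, eligible = TRUE, early = NULL) {
  n <- max(length(onset), length(transfer_class))
  data.table::data.table(
    id = seq_len(n),
    age = rep_len(age, n),
    onset_to_door = rep_len(onset, n),
    early_presenter = rep_len(early %||% (onset <= 270), n),
    eligible_evt = rep_len(eligible, n),
    transfer_class = factor(rep_len(transfer_class, n),
                            levels = c("gains_shorter_transfer",
                                       "gains_new_transfer", "unaffected")),
    transfer_minutes_baseline = rep_len(t_base, n),
    transfer_minutes_reconfig = rep_len(t_reco, n)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random dominating anchor pair for property tests: elementwise max/min of
# two random cumulative distributions guarantees first-order dominance
random_effect_model <- function(t_early = 60, t_late = 480) {
  p1 <- as.vector(stats::rgamma(7, 1)); p1 <- p1 / sum(p1)
  p2 <- as.vector(stats::rgamma(7, 1)); p2 <- p2 / sum(p2)
  c1 <- cumsum(p1); c2 <- cumsum(p2)
  ce <- pmax(c1, c2); cl <- pmin(c1, c2)
  treatment_effect_model(anchor_early = diff(c(0, ce)),
                         anchor_late = diff(c(0, cl)),
                         t_early = t_early, t_late = t_late)
}

# independent oracle for the first-event time distribution (death only):
# month-by-month survival products over the (0.25, 5] window with linear
# placement within the event month, then numerical integration of the
# late-period hazard; written without reference to the package's closed
# forms
event_time_cdf_oracle <- function(t, lambda, hr, age, surv) {
  p_month <- 1 - exp(-lambda / 12)
  n_months <- 57L
  surv_m <- c(1, cumprod(rep(1 - p_month, n_months)))  # S at month bounds
  month_bound <- 0.25 + (0:n_months) / 12
  tail_s <- surv_m[n_months + 1L]
  haz <- function(s) surv$gompertz_a * exp(surv$gompertz_b * (age + s)) *
    hr * (1 - surv$late_mortality_reduction)
  vapply(t, function(ti) {
    if (ti <= 0.25) return(0)
    if (ti <= 5) {
      m <- min(findInterval(ti, month_bound), n_months)  # month index >= 1
      frac <- (ti - month_bound[m]) * 12
      s_here <- surv_m[m] - frac * (surv_m[m] - surv_m[m + 1L])
      return(1 - s_here)
    }
    if (ti >= surv$max_age - age) return(1)
    ch <- stats::integrate(haz, 5, ti, rel.tol = 1e-9)$value
    1 - tail_s * exp(-ch)
  }, numeric(1))
}

ks_distance <- function(x, cdf, grid = NULL) {
  if (is.null(grid)) {
    x <- sort(x)
    n <- length(x)
    f <- cdf(x)
    return(max(abs((1:n) / n - f), abs((0:(n - 1)) / n - f)))
  }
  # grid approximation (for oracles that are expensive per evaluation)
  max(abs(stats::ecdf(x)(grid) - cdf(grid)))
}
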