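#' Rescale competing-risk probabilities
#'
#' At the sampled first-event time, the probabilities of death and of
#' deterioration are rescaled to sum to one before a single uniform draw
#' decides the event type: e.g. a 20% chance of death and a 5% chance of
#' deterioration rescale to 0.8 and 0.2.
#'
#' @param p_death,p_det probabilities in \[0, 1\] (vectors of equal length);
#'   their sum must be positive.
#' @return a list with components `death` and `det`, each summing to 1
#'   elementwise with the other.
#' @examples
#' rescale_competing_risks(0.20, 0.05)  # death 0.8, det 0.2
#' @export
rescale_competing_risks <- function(p_death, p_det) {
  stopifnot(length(p_death) == length(p_det))
  if (any(p_death < 0 | p_death > 1 | p_det < 0 | p_det > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  tot <- p_death + p_det
  if (any(tot <= 0, na.rm = TRUE))
    stop("p_death + p_det must be positive (no event possible otherwise)")
  list(death = p_death / tot, det = p_det / tot)
}

#' Deterioration model
#'
#' One possible post-90-day deterioration event per patient, confined to
#' the window (90 days, 5 years\]: a monthly probability of an increase in
#' mRS, fixed at +2 points capped at mRS 5. Monthly probabilities follow
#' the published values for 90-day mRS 0..3 (0.006, 0.004, 0.002, 0.001);
#' mRS 4--5 carry no separate deterioration event (their excess risk is
#' absorbed into mortality), though probabilities for those states may be
#' supplied.
#'
#' @param monthly_prob monthly deterioration probabilities for 90-day mRS
#'   0..3, optionally 0..5; unspecified states get 0.
#' @param increment mRS increase on deterioration.
#' @param max_mrs cap on the post-deterioration state.
#' @param window years after stroke within which deterioration can occur.
#' @return an object of class `deterioration_model`.
#' @export
deterioration_model <- function(monthly_prob = c(0.006, 0.004, 0.002, 0.001),
                                increment = 2, max_mrs = 5,
                                window = c(0.25, 5)) {
  if (length(monthly_prob) < 4L || length(monthly_prob) > 6L)
    stop("monthly_prob must cover mRS 0..3 (optionally up to mRS 5)")
  p <- c(monthly_prob, rep(0, 6 - length(monthly_prob)))
  if (any(p < 0 | p > 1)) stop("monthly probabilities must lie in [0, 1]")
  if (any(diff(p[1:4]) > 0))
    stop("monthly deterioration probabilities must be non-increasing in mRS")
  stopifnot(window[1] >= 0, window[2] > window[1], increment >= 1,
            max_mrs <= 5)
  structure(
    list(monthly_prob = p, increment = increment, max_mrs = max_mrs,
         window = window),
    class = "deterioration_model"
  )
}

#' Long-term survival model
#'
#' Post-90-day survival by 90-day mRS and age: a constant mRS-specific
#' annual death hazard on (0.25, 5\] years, then from year 5 onward a
#' Gompertz background hazard (a proxy for national life-table mortality)
#' multiplied by an mRS-specific hazard ratio and by (1 - 0.25), the 25%
#' late mortality reduction reflecting secular improvement in stroke
#' survival. Lifetimes are truncated at age 100.
#'
#' @param annual_hazard length-6 vector of annual death hazards for 90-day
#'   mRS 0..5 applying on (0.25, 5\] years.
#' @param gompertz_a,gompertz_b background hazard \eqn{a e^{b \cdot age}}
#'   per year; defaults shaped like UK life-table mortality at older ages.
#' @param mrs_hazard_ratio length-6 multiplier on the background hazard
#'   from year 5, non-decreasing in mRS.
#' @param late_mortality_reduction fractional reduction applied to the
#'   late-period hazard (default 0.25).
#' @param max_age truncation age in years (default 100).
#' @return an object of class `survival_model`.
#' @export
survival_model <- function(annual_hazard,
                           gompertz_a = 3.5e-5, gompertz_b = 0.09,
                           mrs_hazard_ratio = c(1, 1.3, 1.8, 2.5, 3.5, 5),
                           late_mortality_reduction = 0.25,
                           max_age = 100) {
  stopifnot(length(annual_hazard) == 6L, all(annual_hazard >= 0),
            length(mrs_hazard_ratio) == 6L, all(mrs_hazard_ratio > 0),
            gompertz_a > 0, gompertz_b > 0,
            late_mortality_reduction >= 0, late_mortality_reduction < 1,
            max_age > 0)
  if (any(diff(mrs_hazard_ratio) < 0))
    stop("mrs_hazard_ratio must be non-decreasing in mRS")
  structure(
    list(annual_hazard = annual_hazard,
         gompertz_a = gompertz_a, gompertz_b = gompertz_b,
         mrs_hazard_ratio = mrs_hazard_ratio,
         late_mortality_reduction = late_mortality_reduction,
         max_age = max_age, t_start = 0.25, t_switch = 5),
    class = "survival_model"
  )
}

#' Late-period hazard at a given age
#'
#' The year-5+ hazard assembly: background Gompertz hazard times the mRS
#' hazard ratio times (1 - late mortality reduction).
#'
#' @param surv a [survival_model()].
#' @param mrs 90-day mRS states 0..5 (vector).
#' @param age current ages in years (vector).
#' @return hazard per year.
#' @export
late_hazard <- function(surv, mrs, age) {
  surv$gompertz_a * exp(surv$gompertz_b * age) *
    surv$mrs_hazard_ratio[mrs + 1L] * (1 - surv$late_mortality_reduction)
}

# cumulative late-period hazard from time t0 to t (years post-stroke),
# for age at stroke `age`; vectorised
late_cum_hazard <- function(surv, mrs, age, t0, t) {
  cmult <- surv$gompertz_a * surv$mrs_hazard_ratio[mrs + 1L] *
    (1 - surv$late_mortality_reduction)
  b <- surv$gompertz_b
  (cmult / b) * (exp(b * (age + t)) - exp(b * (age + t0)))
}

#' Death-only survival function
#'
#' Probability of surviving beyond `t` years post-stroke for a 90-day
#' survivor in state `mrs` aged `age` at stroke, under the death process
#' alone (deterioration excluded). Survival is 1 up to the 90-day boundary
#' and 0 at the age-100 horizon.
#'
#' @param surv a [survival_model()].
#' @param t years post-stroke (vector).
#' @param mrs 90-day mRS state(s) 0..5.
#' @param age age(s) at stroke.
#' @return survival probabilities.
#' @export
survival_prob <- function(surv, t, mrs, age) {
  n <- max(length(t), length(mrs), length(age))
  t <- rep_len(t, n); mrs <- rep_len(mrs, n); age <- rep_len(age, n)
  lam <- surv$annual_hazard[mrs + 1L]
  t1 <- clamp(t, surv$t_start, surv$t_switch)
  ch <- lam * (t1 - surv$t_start)
  late <- t > surv$t_switch
  if (any(late))
    ch[late] <- ch[late] + late_cum_hazard(surv, mrs[late], age[late],
                                           surv$t_switch, t[late])
  s <- exp(-ch)
  s[t >= surv$max_age - age] <- 0
  s
}

#' Death-only survival quantile (inverse CDF)
#'
#' Closed-form inverse of [survival_prob()]: the time `t` with
#' `S(t) = 1 - p`, capped at the age-100 horizon.
#'
#' @param surv a [survival_model()].
#' @param p cumulative death probabilities in (0, 1) (vector).
#' @param mrs 90-day mRS state(s) 0..5.
#' @param age age(s) at stroke.
#' @param t0 optional start time (years post-stroke) from which the death
#'   process runs, e.g. a deterioration time; default the 90-day boundary.
#' @return death times in years post-stroke.
#' @export
survival_quantile <- function(surv, p, mrs, age, t0 = NULL) {
  n <- max(length(p), length(mrs), length(age))
  p <- rep_len(p, n); mrs <- rep_len(mrs, n); age <- rep_len(age, n)
  t0 <- rep_len(t0 %||% surv$t_start, n)
  stopifnot(all(p > 0 & p < 1), all(t0 >= surv$t_start - 1e-12))
  lam <- surv$annual_hazard[mrs + 1L]
  target <- -log1p(-p)                       # cumulative hazard to reach
  win_start <- pmin(t0, surv$t_switch)
  h_window <- lam * (surv$t_switch - win_start)
  out <- numeric(n)
  inwin <- target <= h_window & lam > 0
  out[inwin] <- win_start[inwin] + target[inwin] / lam[inwin]
  if (any(!inwin)) {
    i <- !inwin
    rem <- target[i] - h_window[i]
    tail_start <- pmax(t0[i], surv$t_switch)
    # hazard already accrued between t_switch and a late start is zero by
    # construction (t0 beyond t_switch only arises post-deterioration,
    # which cannot happen after year 5)
    cmult <- surv$gompertz_a * surv$mrs_hazard_ratio[mrs[i] + 1L] *
      (1 - surv$late_mortality_reduction)
    b <- surv$gompertz_b
    out[i] <- log(exp(b * (age[i] + tail_start)) + b * rem / cmult) / b -
      age[i]
  }
  pmin(out, surv$max_age - age)
}

#' Calibrate default survival hazards to target medians
#'
#' Solves the mRS-specific annual hazards of a [survival_model()] so that
#' the analytic median survival at a reference age reproduces the target
#' medians exactly (published values for a 70-year-old: 8.4, 7.9, 7.2,
#' 3.7, 2.7, 1.3 years for mRS 0..5). Interquartile ranges are not fitted;
#' they are reported as a calibration diagnostic via
#' [survival_calibration_table()].
#'
#' @param medians target median survival in years for mRS 0..5, strictly
#'   decreasing.
#' @param age reference age at stroke (default 70).
#' @param ... further arguments passed to [survival_model()] (e.g.
#'   Gompertz background or hazard ratios).
#' @return a calibrated [survival_model()].
#' @export
calibrate_survival_defaults <- function(medians = c(8.4, 7.9, 7.2, 3.7,
                                                    2.7, 1.3),
                                        age = 70, ...) {
  stopifnot(length(medians) == 6L)
  if (any(medians <= 0)) stop("target medians must be positive")
  if (any(diff(medians) >= 0))
    stop("target medians must be strictly decreasing in mRS")
  proto <- survival_model(annual_hazard = rep(0.1, 6), ...)
  lam <- vapply(0:5, function(s) {
    med <- medians[s + 1]
    if (med <= proto$t_start)
      stop("target median must exceed the 90-day boundary")
    if (med <= proto$t_switch) {
      log(2) / (med - proto$t_start)
    } else {
      h_late <- late_cum_hazard(proto, s, age, proto$t_switch, med)
      lam_s <- (log(2) - h_late) / (proto$t_switch - proto$t_start)
      if (lam_s < 0)
        stop("background mortality alone exceeds the target median for mRS ",
             s, "; reduce the hazard ratio or Gompertz level")
      lam_s
    }
  }, numeric(1))
  survival_model(annual_hazard = lam, ...)
}

#' Survival calibration diagnostic table
#'
#' Analytic median and interquartile survival of a model at a reference
#' age, next to the calibration targets.
#'
#' @param surv a [survival_model()].
#' @param targets a data.frame with columns `mrs`, `median`, `q25`, `q75`
#'   or `NULL` for the published age-70 targets.
#' @param age reference age.
#' @return a data.frame with target and achieved median/IQR per state.
#' @export
survival_calibration_table <- function(surv, targets = NULL, age = 70) {
  targets <- targets %||% data.frame(
    mrs = 0:5,
    median = c(8.4, 7.9, 7.2, 3.7, 2.7, 1.3),
    q25 = c(4.7, 4.3, 3.8, 1.4, 0.92, 0.42),
    q75 = c(14.1, 13.2, 12.3, 7.0, 5.8, 3.6)
  )
  ach <- function(p) survival_quantile(surv, rep(p, 6), 0:5, age)
  data.frame(
    mrs = targets$mrs,
    target_median = targets$median, achieved_median = ach(0.5),
    target_q25 = targets$q25, achieved_q25 = ach(0.25),
    target_q75 = targets$q75, achieved_q75 = ach(0.75)
  )
}

# monthly step probabilities for the combined first-event process
event_month_probs <- function(surv, det, mrs) {
  p_death <- 1 - exp(-surv$annual_hazard[mrs + 1L] / 12)
  p_det <- det$monthly_prob[mrs + 1L]
  list(death = p_death, det = p_det,
       event = 1 - (1 - p_death) * (1 - p_det))
}

#' Sample post-90-day event histories
#'
#' Simulates each 90-day survivor's trajectory: a combined
#' death-or-deterioration process on (90 days, 5 years\] advanced in
#' monthly steps (the published deterioration probabilities are monthly),
#' with the single event uniform inverted through the discrete-time CDF
#' and the event placed uniformly within its month; event type is decided
#' by one uniform against the rescaled competing-risk probabilities. After
#' a deterioration (+2 mRS capped at 5, at most one per history) the death
#' time is re-sampled from the new state and attained age. Survivors of
#' the 5-year window draw a death time from the late-period Gompertz
#' process in closed form. Patients dead at 90 days (mRS 6) are recorded
#' as dying at the 90-day boundary. All times are truncated at age 100.
#'
#' @param mrs90 90-day mRS states 0..6 (vector).
#' @param age ages at stroke (vector).
#' @param surv a [survival_model()].
#' @param det a [deterioration_model()].
#' @param u_event,u_type,u_death optional uniform vectors (one per patient)
#'   driving the first-event time, the event type, and the
#'   post-deterioration death time; drawn internally when `NULL`. Supplying
#'   them enables common random numbers across scenarios.
#' @return a `data.table` with columns `mrs90`, `deterioration_time`,
#'   `mrs_after_deterioration` (NA when no deterioration), `death_time`
#'   (years post-stroke).
#' @export
sample_event_history <- function(mrs90, age, surv, det,
                                 u_event = NULL, u_type = NULL,
                                 u_death = NULL) {
  stopifnot(inherits(surv, "survival_model"),
            inherits(det, "deterioration_model"))
  n <- length(mrs90)
  if (any(mrs90 < 0 | mrs90 > 6)) stop("mrs90 must lie in 0..6")
  age <- rep_len(age, n)
  if (any(age > surv$max_age)) stop("age cannot exceed the maximum lifetime")
  u_event <- u_event %||% runif(n)
  u_type <- u_type %||% runif(n)
  u_death <- u_death %||% runif(n)
  stopifnot(length(u_event) == n, length(u_type) == n, length(u_death) == n)

  det_time <- rep(NA_real_, n)
  det_mrs <- rep(NA_integer_, n)
  death <- numeric(n)
  horizon <- surv$max_age - age

  dead90 <- mrs90 == 6L
  death[dead90] <- pmin(surv$t_start, horizon[dead90])

  alive <- which(!dead90)
  if (length(alive)) {
    s <- mrs90[alive]
    mp <- event_month_probs(surv, det, s)
    n_months <- round((surv$t_switch - surv$t_start) * 12)
    f_win <- 1 - (1 - mp$event)^n_months   # P(first event within window)
    u <- u_event[alive]
    inwin <- u < f_win & mp$event > 0

    t1 <- numeric(length(alive))
    # event within (0.25, 5]: invert the geometric month count, then place
    # the event uniformly within its month using the residual uniform mass
    if (any(inwin)) {
      pe <- mp$event[inwin]
      m <- ceiling(log1p(-u[inwin]) / log1p(-pe))
      m <- pmin(pmax(m, 1L), n_months)
      f_prev <- 1 - (1 - pe)^(m - 1)
      frac <- (u[inwin] - f_prev) / (pe * (1 - pe)^(m - 1))
      t1[inwin] <- surv$t_start + (m - 1 + clamp(frac, 0, 1)) / 12
    }
    # no event by year 5: closed-form draw from the late Gompertz process
    if (any(!inwin)) {
      v <- (u[!inwin] - f_win[!inwin]) / (1 - f_win[!inwin])
      v <- clamp(v, 0, 1 - 1e-15)
      t1[!inwin] <- survival_quantile(
        surv, clamp(v, 1e-15, 1 - 1e-15), s[!inwin], age[alive][!inwin],
        t0 = rep(surv$t_switch, sum(!inwin))
      ) ; # quantile from t_switch with zero window hazard: late-only inverse
    }
    # but survival_quantile from t0 = t_switch measures hazard from the
    # window (zero length), i.e. pure late-period inversion, as intended

    # event type within the window (rescaled competing risks)
    is_det <- rep(FALSE, length(alive))
    if (any(inwin)) {
      rs <- rescale_competing_risks(mp$death[inwin], mp$det[inwin])
      is_det[inwin] <- u_type[alive][inwin] >= rs$death
    }
    # deterioration cannot occur at/after the horizon
    is_det <- is_det & t1 < horizon[alive]

    death_a <- pmin(t1, horizon[alive])
    if (any(is_det)) {
      idx <- which(is_det)
      s2 <- pmin(s[idx] + det$increment, det$max_mrs)
      det_time[alive[idx]] <- t1[idx]
      det_mrs[alive[idx]] <- as.integer(s2)
      death_a[idx] <- survival_quantile(
        surv, clamp(u_death[alive][idx], 1e-15, 1 - 1e-15),
        s2, age[alive][idx], t0 = t1[idx]
      )
      # death strictly after deterioration, still capped at the horizon
      death_a[idx] <- pmin(pmax(death_a[idx], t1[idx] + 1e-9),
                           horizon[alive][idx])
    }
    death[alive] <- death_a
  }

  data.table::data.table(
    mrs90 = as.integer(mrs90),
    deterioration_time = det_time,
    mrs_after_deterioration = det_mrs,
    death_time = death
  )
}
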