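#' Synthetic geography and cohort parameters
#'
#' Parameters of the synthetic two-scenario geography that stands in for the
#' GIS road-distance and hospital data behind the 24-centre versus 30-centre
#' comparison. Defaults reproduce the study conditions: 21,740 patients
#' affected by the reconfiguration, a mean of 2,540 EVT-treated patients of
#' whom 2,316 gain shorter secondary transfers and 222 face a new secondary
#' transfer (the closed centre), mean age 70.
#'
#' Transfer-time distributions are the synthetic replacement for road
#' distances: baseline secondary transfers for the shorter-transfer class
#' are uniform on `shorter_baseline` minutes with reconfigured times a
#' uniform fraction `shorter_fraction` of baseline; the new-transfer class
#' draws reconfigured transfers uniform on `new_transfer` minutes. The
#' defaults calibrate the cohort mean time-to-treatment reduction to about
#' 42 minutes (SD about 60).
#'
#' @param n_affected patients affected by the reconfiguration (21,740).
#' @param mean_evt_treated mean EVT-treated patients per year (2,540).
#' @param n_shorter_transfer expected patients gaining shorter secondary
#'   transfers (2,316).
#' @param n_new_transfer expected patients facing a new secondary transfer
#'   (222).
#' @param mean_age,age_sd cohort age distribution (Normal, truncated to
#'   \[18, 100\]).
#' @param p_early probability of presenting within the early window;
#'   default 440/600 per the published North East England early-presenter
#'   series.
#' @param eligible_mean,eligible_sd Normal parameters of the proportion of
#'   all strokes presenting early with LAO and NIHSS >= 6 (10.6%, SD 0.1%).
#' @param shorter_baseline,shorter_fraction,new_transfer transfer-time
#'   distribution ranges (minutes; fraction) as described above.
#' @return an object of class `geography_params`.
#' @export
geography_params <- function(n_affected = 21740,
                             mean_evt_treated = 2540,
                             n_shorter_transfer = 2316,
                             n_new_transfer = 222,
                             mean_age = 70,
                             age_sd = 12,
                             p_early = 440 / 600,
                             eligible_mean = 0.106,
                             eligible_sd = 0.001,
                             shorter_baseline = c(40, 190),
                             shorter_fraction = c(0.2, 0.8),
                             new_transfer = c(10, 40)) {
  geo <- structure(
    list(
      n_affected = n_affected, mean_evt_treated = mean_evt_treated,
      n_shorter_transfer = n_shorter_transfer,
      n_new_transfer = n_new_transfer,
      mean_age = mean_age, age_sd = age_sd, p_early = p_early,
      eligible_mean = eligible_mean, eligible_sd = eligible_sd,
      shorter_baseline = shorter_baseline,
      shorter_fraction = shorter_fraction,
      new_transfer = new_transfer
    ),
    class = "geography_params"
  )
  validate_geography(geo)
  geo
}

validate_geography <- function(geo) {
  counts <- c(geo$n_affected, geo$mean_evt_treated,
              geo$n_shorter_transfer, geo$n_new_transfer)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      geo$n_affected <= 0 || geo$mean_evt_treated <= 0)
    stop("cohort counts must be positive")
  if (geo$n_shorter_transfer + geo$n_new_transfer > geo$mean_evt_treated)
    stop("n_shorter_transfer + n_new_transfer must not exceed mean_evt_treated")
  if (geo$mean_evt_treated > geo$n_affected)
    stop("mean_evt_treated must not exceed n_affected")
  if (geo$p_early <= 0 || geo$p_early > 1)
    stop("p_early must lie in (0, 1]")
  rng_ok <- function(r) length(r) == 2L && r[1] >= 0 && r[2] >= r[1]
  if (!rng_ok(geo$shorter_baseline) || !rng_ok(geo$shorter_fraction) ||
      !rng_ok(geo$new_transfer))
    stop("transfer-time ranges must be non-negative and ordered")
  if (geo$shorter_fraction[2] >= 1)
    stop("shorter_fraction must be below 1 (reconfigured < baseline)")
  invisible(geo)
}

#' Draw the proportion of strokes eligible for early EVT
#'
#' One Normal(mean, sd) draw per simulation iteration, truncated to (0, 1):
#' the proportion of all strokes presenting early with large-artery
#' occlusion and NIHSS >= 6 (10.6%, SD 0.1%). Sensitivity analyses shift
#' the mean by one percentage point.
#'
#' @param n number of draws.
#' @param mean,sd Normal parameters.
#' @return numeric vector of proportions in (0, 1).
#' @export
draw_eligible_fraction <- function(n = 1, mean = 0.106, sd = 0.001) {
  stopifnot(n >= 1, mean > 0, mean < 1, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Normal truncated to [lo, hi] via inverse CDF
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(clamp(mean, lo, hi), n))
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Generate the affected cohort under both scenarios
#'
#' Generates the full cohort of patients affected by the service
#' reconfiguration: ages, onset-to-door times (early presenters from the
#' quantile-matched sampler; late presenters carried as a count with
#' placeholder times, never simulated), EVT eligibility, and the
#' secondary-transfer class with baseline and reconfigured transfer minutes.
#' Each patient exists once with identical attributes under both scenarios
#' (common random numbers); only transfer minutes differ by scenario.
#'
#' Eligibility among early presenters is calibrated so the expected treated
#' count equals `mean_evt_treated`, scaled proportionally by the drawn
#' eligible fraction relative to its mean. Transfer classes are assigned
#' among eligible patients with probabilities
#' `n_shorter_transfer / mean_evt_treated` and
#' `n_new_transfer / mean_evt_treated`.
#'
#' @param geo a [geography_params()] object.
#' @param sampler an [onset_sampler()]; defaults to the standard anchors.
#' @param eligible_fraction optionally a pre-drawn eligible fraction (one
#'   number); drawn via [draw_eligible_fraction()] when `NULL`.
#' @return a `data.table` with one row per patient and columns `id`, `age`,
#'   `onset_to_door`, `early_presenter`, `eligible_evt`, `transfer_class`
#'   (factor: `gains_shorter_transfer`, `gains_new_transfer`, `unaffected`),
#'   `transfer_minutes_baseline`, `transfer_minutes_reconfig`. The drawn
#'   eligible fraction is attached as attribute `eligible_fraction`.
#' @export
generate_cohort <- function(geo = geography_params(),
                            sampler = onset_sampler(),
                            eligible_fraction = NULL) {
  validate_geography(geo)
  n <- geo$n_affected
  age <- rnorm_trunc(n, geo$mean_age, geo$age_sd, 18, 100)
  early <- runif(n) < geo$p_early
  onset <- numeric(n)
  n_early <- sum(early)
  if (n_early > 0)
    onset[early] <- sample_onset_to_door(sampler, n_early)
  # late presenters: placeholder times beyond the window, never simulated
  if (n_early < n)
    onset[!early] <- runif(n - n_early, sampler$upper_support, 720)

  frac <- eligible_fraction %||%
    draw_eligible_fraction(1, geo$eligible_mean, geo$eligible_sd)
  stopifnot(length(frac) == 1L, frac > 0, frac < 1)
  p_elig <- min(1, geo$mean_evt_treated / (n * geo$p_early) *
                  frac / geo$eligible_mean)
  eligible <- early & runif(n) < p_elig

  cls <- factor(rep("unaffected", n),
                levels = c("gains_shorter_transfer", "gains_new_transfer",
                           "unaffected"))
  n_elig <- sum(eligible)
  p_short <- geo$n_shorter_transfer / geo$mean_evt_treated
  p_new <- geo$n_new_transfer / geo$mean_evt_treated
  if (n_elig > 0) {
    u <- runif(n_elig)
    cls[eligible] <- ifelse(
      u < p_short, "gains_shorter_transfer",
      ifelse(u < p_short + p_new, "gains_new_transfer", "unaffected")
    )
  }

  t_base <- numeric(n)
  t_reco <- numeric(n)
  is_short <- cls == "gains_shorter_transfer"
  is_new <- cls == "gains_new_transfer"
  if (any(is_short)) {
    b <- runif(sum(is_short), geo$shorter_baseline[1], geo$shorter_baseline[2])
    f <- runif(sum(is_short), geo$shorter_fraction[1], geo$shorter_fraction[2])
    t_base[is_short] <- b
    t_reco[is_short] <- b * f
  }
  if (any(is_new))
    t_reco[is_new] <- runif(sum(is_new), geo$new_transfer[1],
                            geo$new_transfer[2])

  out <- data.table::data.table(
    id = seq_len(n),
    age = age,
    onset_to_door = onset,
    early_presenter = early,
    eligible_evt = eligible,
    transfer_class = cls,
    transfer_minutes_baseline = t_base,
    transfer_minutes_reconfig = t_reco
  )
  data.table::setattr(out, "eligible_fraction", frac)
  out
}
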