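#' Validate a 90-day mRS probability distribution
#'
#' A distribution over the seven modified Rankin Scale states 0..6:
#' non-negative entries summing to 1.
#'
#' @param p numeric length-7 vector.
#' @param tol tolerance on the sum.
#' @return `p`, invisibly, after validation.
#' @export
validate_mrs_distribution <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || length(p) != 7L || anyNA(p))
    stop("an mRS distribution is a numeric 7-vector over states 0..6")
  if (any(p < -tol) || any(p > 1 + tol))
    stop("mRS probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-8)
    stop("mRS probabilities must sum to 1")
  invisible(p)
}

# Default anchor distributions. The pooled EVT-trial per-state
# distributions behind the original model are not published; these are
# documented approximations of a treated-early profile and a late-treatment
# profile with minimal residual benefit, constructed to satisfy first-order
# stochastic dominance. All downstream checks are property-based, not tied
# to these values.
default_anchor_early <- function() c(0.15, 0.20, 0.15, 0.16, 0.15, 0.06, 0.13)
default_anchor_late  <- function() c(0.06, 0.12, 0.12, 0.17, 0.21, 0.10, 0.22)

#' Time-dependent 90-day outcome model
#'
#' Ninety-day mRS outcome distributions for EVT-treated patients as a
#' function of onset-to-EVT time, with a linearly declining treatment
#' effect: the distribution equals `anchor_early` at or before `t_early`
#' minutes, `anchor_late` at or after `t_late`, and in between each
#' cumulative probability is interpolated linearly. Interpolating
#' cumulatives (not raw probabilities) keeps every intermediate vector a
#' valid distribution and preserves stochastic dominance, so earlier
#' treatment can never be worse in distribution.
#'
#' @param anchor_early,anchor_late mRS 7-vectors; `anchor_early` must
#'   first-order stochastically dominate `anchor_late` (cumulative
#'   probability of mRS <= k at least as large for every k).
#' @param t_early,t_late anchor times in minutes, `t_early < t_late`.
#' @return an object of class `treatment_effect_model`.
#' @export
treatment_effect_model <- function(anchor_early = default_anchor_early(),
                                   anchor_late = default_anchor_late(),
                                   t_early = 60, t_late = 480) {
  validate_mrs_distribution(anchor_early)
  validate_mrs_distribution(anchor_late)
  if (t_early >= t_late) stop("t_early must be below t_late")
  cum_e <- cumsum(anchor_early)
  cum_l <- cumsum(anchor_late)
  if (any(cum_e[1:6] < cum_l[1:6] - 1e-12))
    stop("anchor_early must stochastically dominate anchor_late ",
         "(cumulative P(mRS <= k) >= for every k)")
  structure(
    list(anchor_early = anchor_early, anchor_late = anchor_late,
         cum_early = cum_e, cum_late = cum_l,
         t_early = t_early, t_late = t_late),
    class = "treatment_effect_model"
  )
}

# n x 7 matrix of cumulative probabilities at times t
mrs_cumulative_at <- function(t, model) {
  stopifnot(inherits(model, "treatment_effect_model"), all(t > 0))
  w <- clamp((t - model$t_early) / (model$t_late - model$t_early), 0, 1)
  outer(1 - w, model$cum_early) + outer(w, model$cum_late)
}

#' mRS distribution at a given onset-to-EVT time
#'
#' @param t onset-to-EVT times in minutes (vector).
#' @param model a [treatment_effect_model()].
#' @return a `length(t)` x 7 matrix of state probabilities (columns are
#'   mRS 0..6), each row summing to 1.
#' @export
mrs_distribution_at <- function(t, model) {
  cum <- mrs_cumulative_at(t, model)
  p <- cbind(cum[, 1, drop = FALSE], cum[, -1] - cum[, -7, drop = FALSE])
  colnames(p) <- paste0("mrs", 0:6)
  p
}

#' Sample 90-day mRS states
#'
#' Inverse-CDF sampling from the time-dependent outcome distribution. When
#' the same uniform `u` is reused for a patient across scenarios (common
#' random numbers), stochastic dominance guarantees that a shorter
#' onset-to-EVT time can never yield a worse sampled state.
#'
#' @param t onset-to-EVT times in minutes (vector).
#' @param model a [treatment_effect_model()].
#' @param u optional uniforms in (0, 1), one per time; drawn when `NULL`.
#' @return integer vector of mRS states 0..6.
#' @export
sample_mrs90 <- function(t, model, u = NULL) {
  u <- u %||% runif(length(t))
  stopifnot(length(u) == length(t))
  cum <- mrs_cumulative_at(t, model)
  as.integer(rowSums(cum < u))
}

#' Population-level change in the 90-day mRS distribution
#'
#' Mean over iterations of the per-state patient-count difference,
#' reconfigured minus baseline. Before rounding the seven deltas sum to
#' zero in every iteration, because each patient occupies exactly one state
#' per scenario.
#'
#' @param mrs_baseline,mrs_reconfig integer matrices (iterations x
#'   patients) or vectors (a single iteration) of sampled mRS states.
#' @return named numeric 7-vector of mean count deltas (states 0..6).
#' @export
population_mrs_change <- function(mrs_baseline, mrs_reconfig) {
  if (is.vector(mrs_baseline)) mrs_baseline <- matrix(mrs_baseline, nrow = 1)
  if (is.vector(mrs_reconfig)) mrs_reconfig <- matrix(mrs_reconfig, nrow = 1)
  stopifnot(identical(dim(mrs_baseline), dim(mrs_reconfig)))
  counts <- function(m) t(apply(m, 1, function(x) tabulate(x + 1L, 7L)))
  delta <- counts(mrs_reconfig) - counts(mrs_baseline)
  setNames(colMeans(delta), paste0("mrs", 0:6))
}

#' Group mRS count changes into clinical bands
#'
#' Summarises a per-state change vector into the two bands used for
#' headline reporting: independent patients (mRS 0--1) and dependent or
#' dead patients (mRS 3--6).
#'
#' @param delta numeric 7-vector of per-state count changes (states 0..6).
#' @return named numeric vector with elements `independent_0_1` and
#'   `dependent_dead_3_6`.
#' @export
mrs_band_changes <- function(delta) {
  stopifnot(length(delta) == 7L)
  c(independent_0_1 = sum(delta[1:2]), dependent_dead_3_6 = sum(delta[4:7]))
}
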