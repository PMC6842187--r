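#' Discounted year measure
#'
#' Cumulative discounted time from 0 to `t` years under discrete annual
#' discounting: year k (the interval \[k-1, k)) is weighted by
#' (1 + r)^-(k - 1), so the first year is undiscounted and partial years are
#' prorated. This is the accumulator behind both QALY and cost streams.
#'
#' @param t numeric vector of non-negative times in years.
#' @param rate annual discount rate (e.g. 0.035).
#' @return numeric vector, same length as `t`.
#' @examples
#' discounted_years(2, 0.035)       # 1 + 1/1.035
#' discounted_years(2, 0)           # 2
#' @export
discounted_years <- function(t, rate) {
  stopifnot(is.numeric(t), all(t >= 0 | is.na(t)), length(rate) == 1L, rate >= 0)
  if (rate == 0) return(t)
  v <- 1 / (1 + rate)
  m <- floor(t)
  (1 - v^m) / (1 - v) + v^m * (t - m)
}

#' Discounted measure of an interval
#'
#' Discounted duration of the interval \[a, b) under annual discounting from
#' time 0. Empty or inverted intervals contribute 0.
#'
#' @param a,b interval endpoints in years (vectors).
#' @param rate annual discount rate.
#' @return numeric vector.
#' @export
discounted_interval <- function(a, b, rate) {
  b <- pmax(a, b)
  discounted_years(b, rate) - discounted_years(a, rate)
}

# clamp to [lo, hi], vectorised
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(x, y) if (is.null(x)) y else x
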