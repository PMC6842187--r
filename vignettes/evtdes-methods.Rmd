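---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtdes)
```

## What the model does

`evtdes` is a patient-level discrete event simulation (DES) of the question:
what are the clinical and lifetime economic consequences of expanding
endovascular thrombectomy (EVT) provision in England from 24 to 30
comprehensive stroke centres (CSCs)? The reconfiguration changes nothing
about how stroke is treated; it changes *where* patients are relative to an
EVT-capable centre, and therefore how long they wait for the procedure. The
model propagates that single mechanism — time to treatment — through 90-day
disability outcomes on the modified Rankin Scale (mRS, 0 = no symptoms to
6 = death), long-term survival and deterioration, and lifetime costs and
quality-adjusted life years (QALYs) from the payer's perspective.

One simulation iteration draws a parameter set (eligibility, journey times,
costs, utilities), simulates every EVT-eligible early presenter under both
the 24-centre baseline and the 30-centre reconfiguration, and sums the
per-patient marginal QALYs and costs into one point on the
cost-effectiveness plane. Two thousand iterations (the default) trace out
the joint uncertainty; means and 2.5th/97.5th percentiles of the iteration
aggregates are the headline estimates. Ineligible patients are unaffected
by the reconfiguration and are excluded from simulation; the cohort
generator still accounts for them in the population denominators.

## The synthetic geography

The original analysis rests on inputs that are not published: GIS road
distances between small-area centroids and hospitals, 600 consecutive
onset-to-door records from a North East England trust, pooled trial
individual-patient data behind the time-outcome relationship, and two
cohort studies behind the survival curves. The `synthetic` layer of this
package replaces those inputs with generators that reproduce their
*published statistical structure*:

* **Onset-to-door times.** Early presenters' arrival times are drawn from a
  piecewise-linear CDF anchored exactly at the published quartiles
  (60 / 85 / 133 min) and truncated at the 270-min early-presentation
  window. A quantile-matched construction is used deliberately: no
  two-parameter family (e.g. log-normal) can match all three quartiles, and
  the quartiles are the only distributional facts available.
* **The affected cohort.** 21,740 patients are affected by the
  reconfiguration; a mean of 2,540 are treated with EVT, of whom 2,316 gain
  shorter secondary transfers and 222 acquire a new transfer (the one
  closed centre). Because these counts are not algebraically derivable from
  the published eligibility proportion (10.6% of strokes presenting early
  with large-artery occlusion and NIHSS ≥ 6), the generator treats the
  treated-count calibration and the eligibility draw as separate inputs:
  the Normal(0.106, 0.001) draw scales the treated count proportionally
  around 2,540, so the ±1-percentage-point sensitivity analyses propagate
  correctly.
* **Transfer times.** Baseline secondary transfers for the
  shorter-transfer class are uniform on [40, 190] min, with reconfigured
  times a uniform fraction [0.2, 0.8] of baseline; new transfers are
  uniform on [10, 40] min. These ranges were chosen once so that the mean
  (SD) time-to-treatment reduction across treated patients calibrates to
  the published 42 (63) min — the quantity that drives every downstream
  result. A narrower baseline range (e.g. [10, 60] min) cannot reach a
  42-min mean saving: with a fractional reduction of 0.5 on average, the
  class-mean saving tops out near 18 min before the new-transfer patients'
  losses are netted off.

What the synthetic geography does **not** reproduce: absolute per-scenario
times-to-treatment. The published per-scenario medians (195 and 165 min)
are not jointly consistent with the fixed pathway constants and the
transfer-class counts — any drip-and-ship patient pays at least
onset + 60 (door-in-door-out) + 90 (door-to-EVT) minutes — so the package
calibrates the *reduction* distribution and reports per-scenario medians as
diagnostics only. Passing tests therefore demonstrate correct mechanics and
calibrated marginal effects, not agreement with unpublished absolute
journey times. Ages are Normal(70, 12) truncated to [18, 100]: the
published model fixes 90-day outcomes to those of a 70-year-old and varies
age ±5 years in sensitivity analysis; the SD is a free choice, documented
here, that only influences post-90-day survival spread.

## Pathway model

Fixed constants, overridable in configuration: door-in-door-out 60 min,
door-to-EVT 90 min, early window 270 min, and a 30-min reduction between
IVT and EVT when no transfer is required. Drip-and-ship:
`onset_to_evt = onset_to_door + 60 + transfer + 90`. Direct presentation:
`onset_to_evt = onset_to_door + 90 − 30`. The 30-min saving is implemented
as a subtraction from the door-to-EVT interval because only the size of the
reduction, not its mechanism, is stated; attaching it to door-in-door-out
instead would be observationally identical here since direct presenters pay
no DIDO. New-transfer patients present directly at baseline and become
drip-and-ship after reconfiguration. IVT pathways never differ between
scenarios, by construction: onset-to-door is scenario-invariant and no cost
or outcome in scope depends on the IVT time itself.

## 90-day outcomes

Outcomes at 90 days depend only on time to treatment. The model holds two
anchor mRS distributions — treatment at `t_early` = 60 min and at
`t_late` = 480 min — and interpolates *cumulative* probabilities linearly
in between, clamping outside the window. Interpolating cumulatives rather
than raw probabilities guarantees that every intermediate vector is a
valid distribution and that first-order stochastic dominance of the early
anchor is preserved at all intermediate times, which is what makes the
common-random-number coupling coherent: each patient carries one uniform
across both scenarios, so a shorter time to treatment can never produce a
worse sampled state for the same patient in the same iteration.

The per-state anchor distributions of the pooled EVT trials are not
published. The shipped defaults are documented approximations (an
early-treatment profile with 50% mRS ≤ 2, and a late profile with 30%
mRS ≤ 2) satisfying dominance; every test that touches anchors is
property-based (dominance, conservation, coupling monotonicity), not tied
to the default numbers. The anchor window is configurable; only linear
decline is hard-wired, as that is the stated modelling assumption.

## Long-term events

Patients dead at 90 days (mRS 6) are recorded as dying at the 0.25-year
boundary and accrue nothing thereafter. Survivors face a combined
death-or-deterioration process:

* **Window (0.25, 5] years.** The process advances in monthly steps —
  deterioration risk is published as monthly probabilities (0.006, 0.004,
  0.002, 0.001 for 90-day mRS 0–3) — with a monthly death probability
  `1 − exp(−λ/12)` from the state-specific annual hazard λ. One uniform
  per patient is inverted through the discrete-time CDF of the combined
  process and the event is placed uniformly within its month; a second
  uniform decides the type against the rescaled competing-risk
  probabilities (e.g. 20% death and 5% deterioration rescale to 0.8 / 0.2).
  Deterioration adds 2 mRS points capped at 5, occurs at most once, and is
  impossible outside the window; following the parameter table, mRS 4–5
  have no separate deterioration event (their excess risk is carried by
  mortality), though probabilities for those states can be supplied where
  the alternative one-point-increase reading is wanted.
* **After year 5.** Death only, sampled in closed form from a Gompertz
  background hazard `a·e^{b·age}` (a = 3.5 × 10⁻⁵, b = 0.09 — the shape of
  UK life-table mortality at older ages) multiplied by an mRS-specific
  hazard ratio (defaults 1, 1.3, 1.8, 2.5, 3.5, 5) and by 0.75, the 25%
  mortality reduction from year 6 onwards that accounts for secular
  improvement since the source registry. "Year 6 onwards" is read as
  t ≥ 5 years post-stroke, consistent with deterioration being confined to
  the first five years. Lifetimes truncate at age 100.

The published survival curves (spline extrapolations of cohort data) are
unavailable, so the window hazards are *calibrated*: given target medians
at age 70 (8.4, 7.9, 7.2, 3.7, 2.7, 1.3 years for mRS 0–5), the constant
window hazard per state is solved analytically so the model's median
survival matches each target exactly. Interquartile ranges are not fitted —
a single constant hazard per state cannot match three quantiles — and are
reported in the calibration diagnostic table instead; the achieved IQRs
are narrower below and wider above than the targets, the expected signature
of a constant hazard standing in for an early-peaked one. Post-deterioration
death times are re-sampled from the new state and attained age, restarted
at the deterioration time.

## Economics

Utilities per mRS state are beta-distributed (means 0.95, 0.93, 0.83,
0.62, 0.42, 0.11; mRS 6 = 0); first-year and subsequent-year care costs
per state are gamma-distributed with the SE-equals-mean convention (shape
1, scale = mean), EVT procedure cost is gamma(554.86, 16.42) (analytic
mean £9,111; the published rounded mean is £9,116, within 0.1%), and
secondary transfers cost £6.86 per minute (or a £234 per-mission tariff in
sensitivity analysis). Care costs are drawn stochastically by default — the
SE-equals-mean rule implies they vary — with a fixed-cost switch.

Correlation within a parameter family uses a comonotonic copula: one
shared uniform mapped through each state's marginal inverse CDF, followed
by a monotone sort of the utilities. This construction exactly guarantees
the stated constraint that no draw ever assigns a worse state a higher
utility (the marginals alone do not: their quantile functions cross in the
lower tail for about 4% of uniforms). A one-factor Gaussian copula with
configurable correlation is available behind a flag; the sort is applied
either way. Only utilities are sorted — the published cost pattern itself
is non-monotone at mRS 5 and is respected as given.

Accumulation uses discrete annual discounting, default 3.5%/year (the
reference-case rate; the source analysis says only "discounted"): year k
is weighted by (1+r)^−(k−1), so year 1 is undiscounted and partial years
are prorated. QALYs integrate the utility of the occupied state over each
lived interval, switching state at deterioration; costs charge the
first-year rate inside year 1 and the annual-thereafter rate beyond, plus
EVT and ambulance components. Budget impact separates the year-1 marginal
cash flow (EVT + ambulance + first-year care) from discounted marginal
care over years 2–5 only. Net monetary benefit is
`wtp × ΔQALY − ΔCost` with QALY losses valued symmetrically at the
threshold.

## Numerical and design choices

* **Seed hierarchy.** The master seed fixes a stream of per-iteration
  seeds; each iteration reseeds from its own value, so extending a run
  never perturbs earlier iterations and results are bit-reproducible.
* **Common random numbers.** Within an iteration, each patient's 90-day
  outcome uniform and post-90-day event uniforms are shared across the two
  scenarios, making within-patient scenario contrasts coherent and
  lowering the variance of the marginal estimates.
* **Intervals.** 95% intervals are percentile-based (2.5th/97.5th of the
  2000 iteration aggregates); the interval construction in the source is
  unstated, and percentiles are the standard choice for simulation output.
* **ICER vs net benefit.** The ICER is reported but flagged undefined when
  the mean QALY difference is numerically zero; net benefit at £20,000,
  £25,000 and £30,000 per QALY is the headline, matching how the results
  table is organised.
* **Degenerate inputs.** Validation rejects non-monotone onset quartiles,
  non-simplex or non-dominating anchors, inconsistent transfer-class
  counts, non-decreasing survival-median targets, and hazard ratios
  decreasing in mRS. A zero-minute transfer still pays door-in-door-out
  plus full door-to-EVT; an empty willingness-to-pay grid omits the CEAC
  output and nothing else.

## Problem sizes

The bundled test suite exercises the full geometry (21,740-patient
cohorts) for generator checks and distribution tests at 100,000 draws; the
end-to-end engine tests run a scaled geography (2,000 affected / ~250
treated patients) at 2–10 iterations, plus one 200-iteration run on the
full default geography for the report-shape and sign checks. The default
configuration (2,000 iterations, full cohort) completes in well under an
hour on a single core; the scaled runs exist to keep routine testing fast,
and their sizes are stated here so results can be reproduced exactly.

## Limitations

Everything inherited from the published model applies: no stroke mimics,
no late-presenter benefit, no capital costs for new centres, 90-day
outcomes invariant with age, a payer perspective only. On top of that, the
synthetic geography is a statistical stand-in: per-scenario absolute
journey times, regional structure, and any correlation between onset time
and transfer distance are not represented, and the outcome anchors and
survival IQRs are approximations calibrated to published summaries rather
than re-estimated source data. Conclusions from this package are therefore
about the *model mechanism* under the published calibration, not a
re-derivation of the original cohort's inputs.
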