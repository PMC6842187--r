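#' Fixed pathway constants
#'
#' Fixed time assumptions of the treatment pathway: door-in-door-out at the
#' primary stroke centre (60 min), door-to-EVT at the comprehensive centre
#' (90 min), a 30 min reduction between IVT and the EVT procedure when no
#' secondary transfer is required, and the 270 min early-presentation
#' window.
#'
#' @param door_in_door_out minutes spent at the primary centre before
#'   transfer departure.
#' @param door_to_evt minutes from comprehensive-centre door to EVT.
#' @param direct_presentation_reduction minutes saved when presenting
#'   directly to an EVT centre.
#' @param early_window early-presentation cutoff in minutes.
#' @return an object of class `pathway_constants`.
#' @export
pathway_constants <- function(door_in_door_out = 60,
                              door_to_evt = 90,
                              direct_presentation_reduction = 30,
                              early_window = 270) {
  if (any(c(door_in_door_out, door_to_evt, direct_presentation_reduction,
            early_window) <= 0))
    stop("pathway constants must be strictly positive")
  if (direct_presentation_reduction >= door_to_evt)
    stop("direct_presentation_reduction must be below door_to_evt")
  structure(
    list(door_in_door_out = door_in_door_out, door_to_evt = door_to_evt,
         direct_presentation_reduction = direct_presentation_reduction,
         early_window = early_window),
    class = "pathway_constants"
  )
}

#' Onset-to-EVT time for given transfer requirements
#'
#' Core pathway arithmetic, vectorised. Patients requiring a secondary
#' transfer pay door-in-door-out, the transfer journey and door-to-EVT on
#' top of onset-to-door; direct presenters pay door-to-EVT less the
#' direct-presentation reduction. A zero-minute transfer still pays
#' door-in-door-out and full door-to-EVT.
#'
#' @param onset_to_door minutes from onset to first hospital door.
#' @param transfer_minutes secondary-transfer journey minutes (0 when no
#'   transfer is required).
#' @param required_transfer logical; whether a secondary transfer occurs.
#' @param constants a [pathway_constants()] object.
#' @return a `data.table` with columns `onset_to_evt`, `required_transfer`,
#'   `ambulance_minutes`.
#' @export
pathway_times <- function(onset_to_door, transfer_minutes, required_transfer,
                          constants = pathway_constants()) {
  stopifnot(inherits(constants, "pathway_constants"),
            all(transfer_minutes >= 0), all(onset_to_door >= 0))
  onset_to_evt <- ifelse(
    required_transfer,
    onset_to_door + constants$door_in_door_out + transfer_minutes +
      constants$door_to_evt,
    onset_to_door + constants$door_to_evt -
      constants$direct_presentation_reduction
  )
  data.table::data.table(
    onset_to_evt = onset_to_evt,
    required_transfer = required_transfer,
    ambulance_minutes = ifelse(required_transfer, transfer_minutes, 0)
  )
}

# transfer requirement by class and scenario: the shorter-transfer class is
# drip-and-ship in both scenarios; the new-transfer class presents directly
# at baseline (their centre existed) and transfers after reconfiguration;
# unaffected treated patients present directly in both scenarios.
transfer_required <- function(transfer_class, scenario) {
  if (scenario == "baseline") {
    transfer_class == "gains_shorter_transfer"
  } else {
    transfer_class %in% c("gains_shorter_transfer", "gains_new_transfer")
  }
}

#' Compute per-patient pathway times for one scenario
#'
#' Applies the fixed pathway constants to eligible early presenters under
#' the given scenario. Onset-to-door and IVT pathways are identical across
#' scenarios by construction; only secondary transfers differ.
#'
#' @param cohort a cohort from [generate_cohort()], restricted to (or
#'   containing only) EVT-eligible early presenters.
#' @param scenario `"baseline"` (24 centres) or `"reconfigured"` (30).
#' @param constants a [pathway_constants()] object.
#' @return a `data.table` with columns `id`, `scenario`, `onset_to_evt`,
#'   `required_transfer`, `ambulance_minutes`.
#' @export
compute_pathway <- function(cohort, scenario = c("baseline", "reconfigured"),
                            constants = pathway_constants()) {
  scenario <- match.arg(scenario)
  el <- cohort[cohort$eligible_evt, ]
  if (any(!el$early_presenter) ||
      any(el$onset_to_door > constants$early_window))
    stop("late presenters cannot enter the EVT pathway")
  transfer <- if (scenario == "baseline") el$transfer_minutes_baseline
              else el$transfer_minutes_reconfig
  req <- transfer_required(el$transfer_class, scenario)
  pt <- pathway_times(el$onset_to_door, transfer, req, constants)
  data.table::data.table(id = el$id, scenario = scenario, pt)
}

#' Per-patient treatment-time reduction
#'
#' Difference in onset-to-EVT minutes, baseline minus reconfigured:
#' positive when the reconfiguration speeds up treatment, negative for
#' patients who acquire a new secondary transfer.
#'
#' @inheritParams compute_pathway
#' @return numeric vector, one value per eligible patient.
#' @export
treatment_time_delta <- function(cohort, constants = pathway_constants()) {
  base <- compute_pathway(cohort, "baseline", constants)
  reco <- compute_pathway(cohort, "reconfigured", constants)
  base$onset_to_evt - reco$onset_to_evt
}
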