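#' Medical cost of one EMS-attended overdose
#'
#' The full systems cost of one overdose attended by emergency medical
#' services: ambulance call-out fee, emergency-department visit, physician
#' assessment (inflation-adjusted), one nasal naloxone kit, plus the
#' expected hospitalization cost (admission probability x admission cost).
#' Under the default 2022 CAD profile this is
#' 518 + 1061 + 196.83 + 125 + 0.33 x 7803 = $4,475.82.
#'
#' @param params A [cost_parameters()] object.
#' @return Cost per EMS-attended overdose, CAD (unrounded).
#' @export
per_ems_overdose_cost <- function(params) {
  stopifnot(inherits(params, "cost_params"))
  params$ems_fee + params$ed_visit_cost + params$physician_fee +
    params$naloxone_cost +
    params$hospitalization_prob * params$hospitalization_cost
}

#' Total medical-services cost (TMSc) per period
#'
#' Prices each period's overdose responses:
#' `TMSc = t_ems x per_ems_overdose_cost + t_fc x ems_fee + t_cr x community_response_cost`.
#' EMS-attended overdoses carry the full ambulance / ED / physician /
#' naloxone / expected-admission pathway; false-positive call-outs incur the
#' ambulance fee only; community-based responses cost one naloxone kit.
#' EMS call-outs for non-overdose emergencies are tallied but not priced.
#' Each component is rounded half-up to cents, and the total is the exact
#' sum of the rounded components.
#'
#' @param tally A per-period tally from [tally_calls()].
#' @param params A [cost_parameters()] object.
#' @return A tibble with one row per period: `period`, `operating_cost`,
#'   the five cost components (`ambulance_component`, `ed_component`,
#'   `hospitalization_component`, `false_positive_component`,
#'   `community_component`) and their sum `medical_cost`. Periods without an
#'   entry in `params$operating_cost_by_period` get `NA` operating cost.
#' @examples
#' profile <- cba_profile("nors2022")
#' medical_services_cost(tally_calls(nors_fixture()), profile$cost)
#' @export
medical_services_cost <- function(tally, params) {
  stopifnot(inherits(params, "cost_params"))
  op <- params$operating_cost_by_period
  tally |>
    dplyr::transmute(
      period = .data$period,
      operating_cost = unname(op[.data$period]),
      ambulance_component = round_cents(.data$t_ems * params$ems_fee),
      ed_component = round_cents(.data$t_ems * (params$ed_visit_cost +
                                                  params$physician_fee +
                                                  params$naloxone_cost)),
      hospitalization_component = round_cents(
        .data$t_od * params$hospitalization_prob * params$hospitalization_cost),
      false_positive_component = round_cents(.data$t_fc * params$ems_fee),
      community_component = round_cents(.data$t_cr * params$community_response_cost),
      medical_cost = .data$ambulance_component + .data$ed_component +
        .data$hospitalization_component + .data$false_positive_component +
        .data$community_component
    )
}

#' Total cost of false-positive EMS call-outs
#'
#' Cost of ambulances dispatched for assumed emergencies that were not
#' overdoses: `t_fc x ems_fee`, summed over all periods in the tally.
#'
#' @inheritParams medical_services_cost
#' @return Total false-positive call-out cost, CAD.
#' @export
false_positive_cost <- function(tally, params) {
  stopifnot(inherits(params, "cost_params"))
  round_cents(sum(tally$t_fc) * params$ems_fee)
}

#' Healthcare savings from community-based responses
#'
#' Each overdose reversed by a nearby community responder (with a naloxone
#' kit) instead of EMS avoids the full EMS pathway cost:
#' `savings = n x (per_ems_overdose_cost - community_response_cost)`.
#'
#' @param n_community Number of community-based overdose responses.
#' @param params A [cost_parameters()] object.
#' @return A one-row tibble: `n_responses`, `per_response` (CAD saved per
#'   response) and `total` (CAD).
#' @examples
#' community_savings(11, cba_profile("nors2022")$cost)
#' @export
community_savings <- function(n_community, params) {
  check_nonneg(n_community, "n_community")
  diff <- per_ems_overdose_cost(params) - params$community_response_cost
  tibble(
    n_responses = n_community,
    per_response = round_cents(diff),
    total = round_cents(n_community * diff)
  )
}
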