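# Unit-price costing helpers. These validate the packaged per-month costs;
# the shipped config files carry the authoritative monthly values.

#' Dosing rule for drug-acquisition costing
#'
#' Describes how a drug is bought and given: vial price and size, dose per
#' administration (flat mg or mg/m2 scaled by body surface area), and the
#' administration schedule. Whole vials are always billed (ceiling rounding,
#' no vial sharing).
#'
#' @param unit_price USD per vial.
#' @param vial_size Vial content, mg.
#' @param dose Dose per administration, mg (or mg/m2 when `per_bsa`).
#' @param per_bsa Is `dose` per m2 of body surface area?
#' @param administrations_per_cycle Administrations in one treatment cycle.
#' @param cycle_days Length of the treatment cycle in days.
#' @param bsa Body surface area, m2 (default 1.72).
#' @return A `dosing_rule` object.
#' @export
dosing_rule <- function(unit_price, vial_size, dose, per_bsa = FALSE,
                        administrations_per_cycle = 1, cycle_days = 21,
                        bsa = 1.72) {
  assert_scalar_number(unit_price, "unit_price", min = 0)
  assert_scalar_number(vial_size, "vial_size", min = 1e-12)
  assert_scalar_number(dose, "dose", min = 1e-12)
  assert_scalar_number(administrations_per_cycle, "administrations_per_cycle",
                       min = 1)
  assert_scalar_number(cycle_days, "cycle_days", min = 1e-12)
  assert_scalar_number(bsa, "bsa", min = 1e-12)
  structure(list(unit_price = unit_price, vial_size = vial_size, dose = dose,
                 per_bsa = isTRUE(per_bsa),
                 administrations_per_cycle = administrations_per_cycle,
                 cycle_days = cycle_days, bsa = bsa),
            class = "dosing_rule")
}

#' Monthly drug-acquisition cost from a dosing rule
#'
#' Cost per administration is `ceiling(required_mg / vial_size) * unit_price`
#' with `required_mg = dose * bsa` for per-BSA dosing. The model month is
#' 28 days (4 weeks), so a q21d schedule contributes `28/21` administrations
#' per month: pembrolizumab 200 mg q21d from 100 mg vials at $2,763.80 gives
#' `2 * 2763.80 * 28/21 = 7370.13` USD/month.
#'
#' @param rule A [dosing_rule()].
#' @param days_per_month Days in a model month (default 28).
#' @return Cost in USD per month.
#' @export
monthly_drug_cost <- function(rule, days_per_month = 28) {
  if (!inherits(rule, "dosing_rule"))
    stop_validation("`rule` must be a dosing_rule")
  required_mg <- if (rule$per_bsa) rule$dose * rule$bsa else rule$dose
  per_admin <- ceiling(required_mg / rule$vial_size) * rule$unit_price
  per_admin * rule$administrations_per_cycle * days_per_month / rule$cycle_days
}

#' Grade >= 3 adverse-event profile
#'
#' @param ae_name Character vector of event names.
#' @param probability Per-patient probability of a grade 3/4 event (fraction).
#' @param cost_per_event Management cost per event, USD; `NA` when no unit
#'   cost is available (such events are excluded from the expected cost).
#' @return An `ae_profile` data frame.
#' @export
ae_profile <- function(ae_name = character(), probability = numeric(),
                       cost_per_event = numeric()) {
  if (length(ae_name) != length(probability) ||
      length(ae_name) != length(cost_per_event))
    stop_validation("ae_profile columns must have equal length")
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop_validation("AE probabilities must lie in [0, 1]")
  if (any(cost_per_event < 0, na.rm = TRUE))
    stop_validation("AE costs must be non-negative")
  structure(data.frame(ae_name = as.character(ae_name),
                       probability = as.numeric(probability),
                       cost_per_event = as.numeric(cost_per_event),
                       stringsAsFactors = FALSE),
            class = c("ae_profile", "data.frame"))
}

#' Expected adverse-event management cost per month
#'
#' Sum of probability times per-event cost over the profile, charged as a
#' constant monthly cost while on treatment (PFS state). Events without a
#' unit cost are dropped. The packaged configs carry the published monthly
#' AE costs directly; this helper reconstructs them from unit costs and is
#' used for validation.
#'
#' @param profile An [ae_profile()].
#' @return USD per month.
#' @export
expected_ae_cost_per_month <- function(profile) {
  if (!inherits(profile, "ae_profile"))
    stop_validation("`profile` must be an ae_profile")
  if (nrow(profile) == 0L) return(0)
  keep <- !is.na(profile$cost_per_event)
  sum(profile$probability[keep] * profile$cost_per_event[keep])
}

#' Trial safety and unit-cost inputs
#'
#' `keynote181_ae_profile()` returns the grade 3/4 adverse-event rates
#' observed in the KEYNOTE-181 safety population for one arm, joined to 2021
#' West China Hospital per-event management costs (USD at 6.4831 CNY/USD).
#' Diarrhea and alopecia have no unit cost and carry `NA`.
#' `keynote181_dosing()` returns the dosing rule used to validate the
#' packaged monthly drug costs.
#'
#' @param arm `"pembrolizumab"` or `"chemotherapy"`.
#' @return An [ae_profile()] / a [dosing_rule()].
#' @export
keynote181_ae_profile <- function(arm) {
  arm <- match_choice(arm, arms(), "arm")
  events <- c("Fatigue", "Decreased appetite", "Asthenia", "Nausea",
              "Diarrhea", "Vomiting", "Anemia", "Alopecia",
              "Neutrophil count decreased", "Peripheral sensory neuropathy",
              "WBC count decreased", "Neutropenia")
  pct <- if (arm == "pembrolizumab")
    c(0.64, 0.64, 1.27, 0.00, 0.64, 0.32, 1.27, 0.00, 0.32, 0.00, 0.00, 0.00)
  else
    c(0.34, 1.01, 1.01, 2.36, 3.04, 2.03, 7.77, 0.34, 9.80, 0.34, 10.14, 7.09)
  cost <- c(214.43, 105.57, 214.43, 98.83, NA, 98.83, 328.90, NA,
            356.31, 17.49, 356.31, 356.31)
  ae_profile(events, pct / 100, cost)
}

#' @rdname keynote181_ae_profile
#' @param drug One of `"pembrolizumab"`, `"paclitaxel"`, `"docetaxel"`,
#'   `"irinotecan"`.
#' @export
keynote181_dosing <- function(drug) {
  drug <- match_choice(drug, c("pembrolizumab", "paclitaxel", "docetaxel",
                               "irinotecan"), "drug")
  switch(drug,
    pembrolizumab = dosing_rule(2763.80, 100, 200, per_bsa = FALSE,
                                administrations_per_cycle = 1, cycle_days = 21),
    paclitaxel = dosing_rule(104.89, 30, 90, per_bsa = TRUE,
                             administrations_per_cycle = 3, cycle_days = 28),
    docetaxel = dosing_rule(200.52, 20, 75, per_bsa = TRUE,
                            administrations_per_cycle = 1, cycle_days = 21),
    irinotecan = dosing_rule(273.50, 100, 180, per_bsa = TRUE,
                             administrations_per_cycle = 1, cycle_days = 14))
}
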