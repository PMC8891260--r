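# Cost model: CapEx from a power-law on scale; OpEx split into fixed
# (annualised CapEx, labour, QC/QA) and variable (materials over batch
# starts -- failed batches consume their materials). Annualised CapEx is
# folded into fixed OpEx; nominal USD, no discounting.

#' Capital investment for a production line
#'
#' Classic power-law estimate
#' \deqn{CapEx = CapEx_{ref} (scale / scale_{ref})^{e}}{CapEx = ref * (scale/ref_scale)^e}
#' with exponent `e < 1` (six-tenths rule by default), so larger lines are
#' cheaper per litre.
#'
#' @param scale Bioreactor working volume in litres (vectorised).
#' @param calibration A `vax_calibration`.
#' @return CapEx in USD.
#' @examples
#' capex_estimate(2000, platform_calibration("avv"))
#' @export
capex_estimate <- function(scale, calibration) {
  if (any(scale <= 0)) abort("`scale` must be positive.")
  calibration$reference_capex_usd *
    (scale / calibration$reference_scale_l)^calibration$capex_exponent
}

# variable material cost of one batch START, per scenario row
material_cost_per_batch <- function(scenarios, calibration) {
  mat <- calibration$materials
  if (identical(mat$basis, "per_gram_rna")) {
    grams <- scenarios$scale * scenarios$titre
    grams * (mat$cap_analogue_g_per_g * scenarios$cap_price + mat$other_usd_per_g)
  } else if (identical(mat$basis, "per_litre_batch")) {
    mat$cost_usd_per_l_batch * scenarios$scale
  } else {
    abort(sprintf("Unknown material basis '%s'.", mat$basis %||% "<missing>"))
  }
}

#' Annual cost structure for each scenario
#'
#' Appends the cost KPIs to a production table:
#' * `capex` -- capital investment of the line at the scenario's scale;
#' * `opex_fixed` -- annualised CapEx (straight-line plus maintenance)
#'   + crew labour at the scenario's basic labour rate over the annual
#'   coverage hours, marked up by the QC/QA share;
#' * `opex_variable` -- material recipe cost times batch \emph{starts}
#'   (failed batches consume their materials before rejection);
#' * `opex_total = opex_fixed + opex_variable`;
#' * `cost_per_dose = opex_total / doses_per_year` (NA and flagged via
#'   `cost_undefined` when annual output is zero).
#'
#' @param production Output of [simulate_production()].
#' @param calibration A `vax_calibration` matching the platform.
#' @return `production` with columns `capex`, `opex_fixed`,
#'   `opex_variable`, `opex_total`, `cost_per_dose`, `cost_undefined`.
#' @examples
#' scen <- sample_scenarios(platform_factors("sarna"), 16)
#' prod <- simulate_production(scen, platform_calibration("sarna"))
#' simulate_costs(prod, platform_calibration("sarna"))
#' @export
simulate_costs <- function(production, calibration = platform_calibration(production$platform[1])) {
  if (production$platform[1] != calibration$platform) {
    abort("Platform mismatch between production table and calibration.")
  }
  labour_cost <- calibration$crew_per_line * production$labour *
    calibration$labour_hours_per_year
  out <- dplyr::mutate(
    production,
    capex = capex_estimate(.data$scale, calibration),
    opex_fixed = calibration$capex_annualisation * .data$capex +
      labour_cost * (1 + .data$qc_share / 100),
    opex_variable = material_cost_per_batch(production, calibration) *
      .data$batch_starts_per_year,
    opex_total = .data$opex_fixed + .data$opex_variable,
    cost_undefined = .data$doses_per_year <= 0,
    cost_per_dose = ifelse(.data$cost_undefined, NA_real_,
                           .data$opex_total / .data$doses_per_year)
  )
  attr(out, "design_meta") <- attr(production, "design_meta")
  attr(out, "factor_set") <- attr(production, "factor_set")
  out
}

#' Cost per dose from a cost structure
#'
#' `opex_total / doses_per_year`; undefined (NA, with a warning) when the
#' annual output is zero.
#'
#' @param opex_total Annual operating cost, USD/yr.
#' @param doses_per_year Annual output, doses/yr.
#' @return USD per dose.
#' @export
cost_per_dose <- function(opex_total, doses_per_year) {
  bad <- doses_per_year <= 0
  if (any(bad)) warn(sprintf("%d scenario(s) have zero output; cost per dose is NA.", sum(bad)))
  ifelse(bad, NA_real_, opex_total / doses_per_year)
}

#' Full KPI table for a scenario design
#'
#' Convenience wrapper running [simulate_production()] and
#' [simulate_costs()], yielding the eight techno-economic KPIs per
#' scenario: CapEx, OpEx, batches/yr, amount/batch, amount/yr,
#' doses/batch, doses/yr, cost/dose.
#'
#' @param scenarios Scenario tibble.
#' @param calibration A `vax_calibration` (defaults to the packaged one for
#'   the scenarios' platform).
#' @return KPI tibble (scenario columns plus production and cost columns).
#' @export
simulate_kpis <- function(scenarios, calibration = platform_calibration(scenarios$platform[1])) {
  simulate_costs(simulate_production(scenarios, calibration), calibration)
}
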