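# Lumped batch production model. The titre factor is already net of
# downstream recovery losses, so amount per batch is simply scale x titre;
# batch failure removes whole released batches but not batch starts.

# RNA amounts are tracked in grams while doses are in micrograms; AVV
# amounts and doses are both in viral particles.
amount_per_dose_unit <- function(platform) {
  if (platform == "avv") 1 else 1e6
}

#' Batch starts per year on a production line
#'
#' Campaign-average scheduling backbone: `operating_days /
#' batch_cycle_days * parallel_lines`. Fractional batches are allowed
#' (campaign averages, matching the linear-extrapolation stance of the
#' capacity projections).
#'
#' @param calibration A `vax_calibration` from [platform_calibration()].
#' @return Batch starts per year (numeric scalar).
#' @examples
#' batches_per_year(platform_calibration("avv"))
#' @export
batches_per_year <- function(calibration) {
  if (calibration$batch_cycle_days <= 0) abort("Batch cycle time must be positive.")
  calibration$operating_days / calibration$batch_cycle_days * calibration$parallel_lines
}

#' Drug-substance amount per batch
#'
#' `scale * titre`, in grams (RNA platforms) or viral particles (AVV). No
#' further loss factor is applied: titre is net of downstream recovery.
#'
#' @param scale Bioreactor working volume in litres.
#' @param titre Product concentration (g/L for RNA, vp/L for AVV), net of
#'   downstream losses.
#' @return Amount per batch, same length as the inputs.
#' @export
amount_per_batch <- function(scale, titre) {
  if (any(scale < 0) || any(titre < 0)) abort("`scale` and `titre` must be non-negative.")
  scale * titre
}

#' Annual production output for each scenario
#'
#' Maps scenarios to the physical output KPIs: batch starts and released
#' batches per year, amount per batch and per year, doses per batch and per
#' year, and specific productivity (doses per year per litre of bioreactor
#' working volume). Released batches are `batch starts * (1 - failure)`;
#' a failed batch yields no product (cGMP lot rejection) but still counts
#' as a start for material consumption in the cost model.
#'
#' @param scenarios Scenario tibble from [sample_scenarios()] or
#'   [baseline_scenario()].
#' @param calibration A `vax_calibration`; must match the scenarios'
#'   platform.
#' @return The scenario tibble with output columns appended:
#'   `batch_starts_per_year`, `batches_released_per_year`,
#'   `amount_per_batch`, `amount_per_year`, `doses_per_batch`,
#'   `doses_per_year`, `specific_productivity`.
#' @examples
#' scen <- sample_scenarios(platform_factors("mrna"), 16)
#' simulate_production(scen, platform_calibration("mrna"))
#' @export
simulate_production <- function(scenarios, calibration = platform_calibration(scenarios$platform[1])) {
  platform <- scenarios$platform[1]
  if (platform != calibration$platform) {
    abort(sprintf("Scenarios are '%s' but calibration is '%s'.",
                  platform, calibration$platform))
  }
  if (any(scenarios$dose <= 0)) abort("Drug-substance amount per dose must be positive.")
  starts <- batches_per_year(calibration)
  conv <- amount_per_dose_unit(platform)
  out <- dplyr::mutate(
    scenarios,
    batch_starts_per_year = starts,
    batches_released_per_year = starts * (1 - .data$failure / 100),
    amount_per_batch = amount_per_batch(.data$scale, .data$titre),
    amount_per_year = .data$amount_per_batch * .data$batches_released_per_year,
    doses_per_batch = .data$amount_per_batch * conv / .data$dose,
    doses_per_year = .data$amount_per_year * conv / .data$dose,
    specific_productivity = .data$doses_per_year / .data$scale
  )
  attr(out, "design_meta") <- attr(scenarios, "design_meta")
  attr(out, "factor_set") <- attr(scenarios, "factor_set")
  out
}

#' Time for one production line to reach a dose target
#'
#' `target / doses_per_year`, in years, excluding QC release lead time.
#' Scenarios with zero annual output are flagged: the time is `Inf` and the
#' logical column `undefined` is set.
#'
#' @param production Output of [simulate_production()].
#' @param target Dose target (default 1e9 doses).
#' @return `production` with columns `time_to_target_years` and
#'   `undefined` appended; the target is recorded in the
#'   `"dose_target"` attribute.
#' @export
time_to_doses <- function(production, target = 1e9) {
  if (target <= 0) abort("`target` must be positive.")
  out <- dplyr::mutate(
    production,
    time_to_target_years = ifelse(.data$doses_per_year > 0,
                                  target / .data$doses_per_year, Inf),
    undefined = .data$doses_per_year <= 0
  )
  if (any(out$undefined)) {
    warn(sprintf("%d scenario(s) have zero annual output; time to target is Inf.",
                 sum(out$undefined)))
  }
  attr(out, "dose_target") <- target
  out
}
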