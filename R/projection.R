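# Capacity projections: linear extrapolation of single-line performance to
# multi-billion dose targets. Economy of scale is deliberately suppressed
# here -- lines are replicated fractionally and CapEx/OpEx scale linearly
# in the number of lines -- because the sampled processes are already at
# production scale and supplier constraints counteract further scale
# economies.

#' Resources required to meet an annual dose target
#'
#' For every scenario, computes the (fractional) number of production lines
#' needed to supply `target` doses per year, and scales scale, batches,
#' CapEx and OpEx linearly in lines. If a fill-to-finish spec is given,
#' fractional filling lines are added to the `_total` figures.
#'
#' @param kpis Per-scenario KPI table from [simulate_kpis()].
#' @param target Annual dose target (default 1e9 doses/yr).
#' @param ff A `vax_ff_spec` from [fill_finish_spec()], or `NULL` for
#'   drug-substance-only accounting.
#' @param integer_lines If `TRUE`, round line counts up to whole lines
#'   (realism option; the default fractional accounting matches the linear
#'   extrapolation used for all reported figures).
#' @return A tibble with one row per scenario: `platform`, `scenario`,
#'   `target_doses`, `lines`, `ff_lines`, `required_scale`,
#'   `batches_per_year`, `capex_ds`, `capex_total`, `opex_ds`,
#'   `opex_total`, `cost_per_dose`, `undefined`.
#' @examples
#' kpis <- simulate_kpis(sample_scenarios(platform_factors("sarna"), 64))
#' project_resources(kpis, 1e9, fill_finish_spec("vial5"))
#' @export
project_resources <- function(kpis, target = 1e9, ff = NULL,
                              integer_lines = FALSE) {
  if (target <= 0) abort("`target` must be positive.")
  undefined <- kpis$doses_per_year <= 0
  if (any(undefined)) {
    warn(sprintf("%d scenario(s) have zero output and cannot meet any target.",
                 sum(undefined)))
  }
  lines <- ifelse(undefined, NA_real_, target / kpis$doses_per_year)
  if (integer_lines) lines <- ceiling(lines)
  ff_lines <- 0
  ff_capex <- 0
  ff_opex <- 0
  if (!is.null(ff)) {
    stopifnot(inherits(ff, "vax_ff_spec"))
    ff_rate <- ff_annual_doses(ff)
    ff_lines <- target / ff_rate
    if (integer_lines) ff_lines <- ceiling(ff_lines)
    ff_capex <- ff_lines * ff$capex_usd
    ff_opex <- ff_lines * (ff$capex_annualisation * ff$capex_usd +
                             ff$opex_fixed_usd_per_year) +
      target / ff$doses_per_container * ff$cost_per_container_usd
  }
  out <- tibble::tibble(
    platform = kpis$platform,
    scenario = kpis$scenario,
    target_doses = target,
    lines = lines,
    ff_lines = ff_lines,
    required_scale = lines * kpis$scale,
    batches_per_year = lines * kpis$batch_starts_per_year,
    capex_ds = lines * kpis$capex,
    capex_total = lines * kpis$capex + ff_capex,
    opex_ds = lines * kpis$opex_total,
    opex_total = lines * kpis$opex_total + ff_opex,
    cost_per_dose = (lines * kpis$opex_total + ff_opex) / target,
    undefined = undefined
  )
  attr(out, "fill_finish") <- if (is.null(ff)) "none" else ff$name
  out
}

#' Annual booster-dose demand
#'
#' Doses per year needed to give `doses_per_person` annual booster doses to
#' the vulnerable population plus frontline personnel.
#'
#' @param vulnerable Vulnerable population size (default 2.2 billion:
#'   people over 60 plus adults with underlying conditions).
#' @param frontline Frontline personnel (default 200 million).
#' @param doses_per_person Annual doses per person (default 1).
#' @return Doses per year.
#' @examples
#' booster_demand()  # 2.4 billion doses/yr
#' @export
booster_demand <- function(vulnerable = 2.2e9, frontline = 2e8,
                           doses_per_person = 1) {
  if (any(c(vulnerable, frontline, doses_per_person) < 0)) {
    abort("Demand inputs must be non-negative.")
  }
  (vulnerable + frontline) * doses_per_person
}

#' Projection distribution for the global demand gap
#'
#' [project_resources()] at the estimated global demand shortfall
#' (11.3 billion doses to reach herd immunity, by default), returning the
#' full per-scenario distribution for summarisation.
#'
#' @inheritParams project_resources
#' @export
global_gap_projection <- function(kpis, target = 11.3e9, ff = NULL) {
  project_resources(kpis, target = target, ff = ff)
}
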