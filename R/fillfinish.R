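# Fill-to-finish: filling formulated drug substance into final containers.
# Three technologies are configured: multi-dose vials (5- or 10-dose),
# blow-fill-seal single-dose units, and 200-dose bags. Lines run
# continuously (525,600 min/yr) with overall equipment effectiveness (OEE)
# absorbing all downtime.

#' Annual dose throughput of a fill-to-finish line
#'
#' `containers_per_minute * oee * operating_minutes * doses_per_container`.
#'
#' @param spec A `vax_ff_spec` from [fill_finish_spec()].
#' @return Doses per year (numeric scalar).
#' @examples
#' ff_annual_doses(fill_finish_spec("vial10"))  # ~1.26 billion doses/yr
#' @export
ff_annual_doses <- function(spec) {
  stopifnot(inherits(spec, "vax_ff_spec"))
  spec$containers_per_minute * spec$oee * spec$operating_minutes *
    spec$doses_per_container
}

#' Fill-to-finish cost per dose
#'
#' Per-dose cost of filling with fractional line utilisation: the line's
#' annualised CapEx and fixed operating cost are spread over its annual
#' throughput, plus the container cost per dose. Under fractional-line
#' accounting this is independent of the volume filled, which keeps
#' projections linear in the dose target.
#'
#' @param spec A `vax_ff_spec`.
#' @return USD per dose.
#' @examples
#' ff_cost_per_dose(fill_finish_spec("vial5"))
#' @export
ff_cost_per_dose <- function(spec) {
  stopifnot(inherits(spec, "vax_ff_spec"))
  capacity <- ff_annual_doses(spec)
  if (capacity <= 0) {
    warn("Fill-finish line has zero throughput; cost per dose undefined.")
    return(NA_real_)
  }
  fixed <- spec$capex_annualisation * spec$capex_usd + spec$opex_fixed_usd_per_year
  fixed / capacity + spec$cost_per_container_usd / spec$doses_per_container
}

#' Locate the production bottleneck
#'
#' Compares a drug-substance production rate with a fill-to-finish line
#' rate and returns the limiting stage and rate. Ties go to drug substance
#' by convention.
#'
#' @param ds_rate Drug-substance production rate, doses/yr (vectorised).
#' @param ff_rate Fill-to-finish rate, doses/yr.
#' @return A tibble with columns `ds_rate`, `ff_rate`, `stage`
#'   (`"drug_substance"` or `"fill_finish"`) and `limiting_rate`.
#' @examples
#' locate_bottleneck(5e8, ff_annual_doses(fill_finish_spec("vial10")))
#' @export
locate_bottleneck <- function(ds_rate, ff_rate) {
  if (any(ds_rate < 0) || any(ff_rate < 0)) abort("Rates must be non-negative.")
  tibble::tibble(
    ds_rate = ds_rate,
    ff_rate = ff_rate,
    stage = ifelse(ds_rate <= ff_rate, "drug_substance", "fill_finish"),
    limiting_rate = pmin(ds_rate, ff_rate)
  )
}
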