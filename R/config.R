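#' Load the platform configuration
#'
#' Reads the packaged (or a user-supplied) JSON configuration holding the
#' lumped model's calibration constants: batch cycle times and operating
#' days, reference CapEx and the power-law scaling exponent, crew sizes,
#' material recipes and prices, fill-to-finish line specifications and the
#' demand targets. These constants were calibrated once against published
#' baseline and design-median anchors for the three platforms and are
#' frozen; they live in configuration, never in code.
#'
#' @param path Optional path to a JSON config file; defaults to the
#'   packaged configuration.
#' @return A nested list with class `vax_config`.
#' @examples
#' cfg <- vax_config()
#' names(cfg$platforms)
#' @export
vax_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "platform_config.json", package = "vaxtea")
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (field in c("capex_exponent", "capex_annualisation",
                  "labour_hours_per_year", "platforms", "fill_finish")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("Config '%s' is missing required field '%s'.", path, field))
    }
  }
  class(cfg) <- c("vax_config", class(cfg))
  cfg
}

#' Calibration constants for one platform
#'
#' Pulls one platform's scheduling and cost constants out of a
#' configuration, with validity checks.
#'
#' @param platform `"avv"`, `"mrna"` or `"sarna"`.
#' @param config A `vax_config` (defaults to the packaged one).
#' @return A list with class `vax_calibration`: `platform`,
#'   `batch_cycle_days`, `operating_days`, `parallel_lines`,
#'   `reference_scale_l`, `reference_capex_usd`, `capex_exponent`,
#'   `capex_annualisation`, `crew_per_line`, `labour_hours_per_year`,
#'   `materials`.
#' @export
platform_calibration <- function(platform, config = vax_config()) {
  platform <- match_platform(platform)
  pc <- config$platforms[[platform]]
  if (is.null(pc)) abort(sprintf("Config has no platform '%s'.", platform))
  cal <- list(
    platform = platform,
    batch_cycle_days = pc$batch_cycle_days,
    operating_days = pc$operating_days,
    parallel_lines = pc$parallel_lines %||% 1,
    reference_scale_l = pc$reference_scale_l,
    reference_capex_usd = pc$reference_capex_usd,
    capex_exponent = config$capex_exponent,
    capex_annualisation = config$capex_annualisation,
    crew_per_line = pc$crew_per_line,
    labour_hours_per_year = config$labour_hours_per_year,
    materials = pc$materials
  )
  if (!is.numeric(cal$batch_cycle_days) || cal$batch_cycle_days <= 0) {
    abort("`batch_cycle_days` must be positive.")
  }
  if (cal$operating_days <= 0 || cal$operating_days > 365) {
    abort("`operating_days` must lie in (0, 365].")
  }
  class(cal) <- "vax_calibration"
  cal
}

#' Fill-to-finish line specification
#'
#' @param technology One of `"vial5"`, `"vial10"`, `"bfs1"`, `"bag200"`, or
#'   `"none"` (returns `NULL`: drug-substance-only accounting).
#' @param config A `vax_config`.
#' @return A list with class `vax_ff_spec` (fields `technology`,
#'   `doses_per_container`, `containers_per_minute`, `oee`,
#'   `operating_minutes`, `cost_per_container_usd`, `capex_usd`,
#'   `opex_fixed_usd_per_year`, `capex_annualisation`), or `NULL`.
#' @examples
#' fill_finish_spec("vial10")
#' @export
fill_finish_spec <- function(technology, config = vax_config()) {
  if (identical(technology, "none") || is.null(technology)) return(NULL)
  spec <- config$fill_finish[[technology]]
  if (is.null(spec)) {
    abort(sprintf("Unknown fill-finish technology '%s'; expected one of %s or 'none'.",
                  technology, paste(names(config$fill_finish), collapse = ", ")))
  }
  spec$name <- technology
  spec$capex_annualisation <- config$capex_annualisation
  if (spec$oee <= 0 || spec$oee > 1) abort("OEE must lie in (0, 1].")
  class(spec) <- "vax_ff_spec"
  spec
}
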