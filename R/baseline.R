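#' Baseline cost per dose including fill-to-finish
#'
#' Deterministic cost per dose at a platform's central-value (baseline)
#' scenario: drug-substance OpEx per dose at the baseline line output plus
#' the fill-to-finish cost per dose of the chosen technology. This is the
#' headline "cost per dose in final containers" figure for each platform.
#'
#' @param platform `"avv"`, `"mrna"` or `"sarna"`.
#' @param fill_finish Fill-finish technology key (default 10-dose vials for
#'   AVV, 5-dose vials for the RNA platforms), or `"none"`.
#' @param config A `vax_config`.
#' @return One-row tibble: `platform`, `fill_finish`, `doses_per_year`
#'   (baseline line output), `ds_cost_per_dose`, `ff_cost_per_dose`,
#'   `cost_per_dose` (total).
#' @examples
#' baseline_cost_per_dose("avv")   # 10-dose vials
#' baseline_cost_per_dose("sarna") # 5-dose vials
#' @export
baseline_cost_per_dose <- function(platform, fill_finish = NULL,
                                   config = vax_config()) {
  platform <- match_platform(platform)
  fill_finish <- fill_finish %||% ifelse(platform == "avv", "vial10", "vial5")
  cal <- platform_calibration(platform, config)
  ff <- fill_finish_spec(fill_finish, config)
  kpi <- simulate_kpis(baseline_scenario(platform), cal)
  ffd <- if (is.null(ff)) 0 else ff_cost_per_dose(ff)
  tibble::tibble(
    platform = platform,
    fill_finish = fill_finish,
    doses_per_year = kpi$doses_per_year,
    ds_cost_per_dose = kpi$cost_per_dose,
    ff_cost_per_dose = ffd,
    cost_per_dose = kpi$cost_per_dose + ffd
  )
}
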