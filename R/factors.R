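#' Uncertain input factors for a vaccine production platform
#'
#' Returns the packaged uncertainty model for one platform as a tibble with
#' one row per uncertain factor, in the fixed order in which sensitivity
#' indices are reported: scale, failure rate, titre, (cap analogue price for
#' the RNA platforms), labour rate, drug-substance amount per dose, QC cost
#' share. The AVV set has six factors: cell-free capping reagents do not
#' exist in adenovirus production, so there is no cap-analogue price factor.
#'
#' Titre is defined net of downstream recovery losses: a single factor
#' carries the combined variation of bioreactor titre and purification
#' yield, so no separate recovery factor appears anywhere in the model.
#'
#' @param platform `"avv"`, `"mrna"` or `"sarna"`.
#' @param path Optional path to a JSON factor-set file with the same layout
#'   as the packaged `factor_sets.json`; defaults to the packaged
#'   uncertainty model.
#' @return A tibble with columns `platform`, `name`, `units`, `dist`
#'   (`"triangular"` or `"uniform"`), `low`, `mode` (`NA` for uniform) and
#'   `high`.
#' @examples
#' platform_factors("sarna")
#' @export
platform_factors <- function(platform, path = NULL) {
  platform <- match_platform(platform)
  path <- path %||% system.file("extdata", "factor_sets.json", package = "vaxtea")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw[[platform]])) {
    abort(sprintf("Factor file '%s' has no entry for platform '%s'.", path, platform))
  }
  fs <- tibble::as_tibble(raw[[platform]])
  fs$mode <- as.numeric(fs$mode)  # JSON null -> NA
  fs <- dplyr::mutate(fs, platform = platform, .before = 1)
  validate_factor_set(fs)
  fs
}

validate_factor_set <- function(factors) {
  required <- c("platform", "name", "units", "dist", "low", "mode", "high")
  missing <- setdiff(required, names(factors))
  if (length(missing) > 0) {
    abort(paste0("Factor set is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(factors$dist %in% c("triangular", "uniform"))) {
    abort("Factor distributions must be 'triangular' or 'uniform'.")
  }
  if (any(factors$low >= factors$high)) {
    abort("Every factor needs `low < high`.")
  }
  tri <- factors$dist == "triangular"
  if (any(is.na(factors$mode[tri]))) {
    abort("Triangular factors need a mode.")
  }
  if (any(factors$mode[tri] < factors$low[tri] | factors$mode[tri] > factors$high[tri])) {
    abort("Triangular factors need `low <= mode <= high`.")
  }
  if (anyDuplicated(factors$name)) abort("Factor names must be unique.")
  invisible(factors)
}

# central (baseline) value of each factor: mode for triangular factors,
# range midpoint for uniform ones
factor_central_values <- function(factors) {
  ifelse(factors$dist == "triangular", factors$mode,
         (factors$low + factors$high) / 2)
}

#' Baseline scenario at the central factor values
#'
#' One-row scenario tibble at each factor's most probable value (mode of the
#' triangular factors, midpoint of the uniform ones), e.g. 2000 L / 2.5e14
#' vp/L / 5e10 vp per dose for AVV. This is the deterministic operating
#' point around which the uncertainty design spreads.
#'
#' @inheritParams platform_factors
#' @param factors Optional factor set (as from [platform_factors()]).
#' @return A one-row scenario tibble (see [sample_scenarios()] for layout).
#' @examples
#' baseline_scenario("avv")
#' @export
baseline_scenario <- function(platform, factors = NULL) {
  platform <- match_platform(platform)
  factors <- factors %||% platform_factors(platform)
  validate_factor_set(factors)
  vals <- setNames(as.list(factor_central_values(factors)), factors$name)
  scen <- tibble::as_tibble(c(list(platform = platform, scenario = 1L), vals))
  new_scenario_set(scen, factors,
                   meta = list(generator = "baseline", n = 1L, skip = NA_integer_))
}
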