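# Distribution summaries and pipeline orchestration. Quantile convention:
# linear interpolation between order statistics (R type 7) throughout.

#' Summarise a simulated KPI distribution
#'
#' Median, quartiles and 5th/95th percentiles of a sample. Medians and
#' IQRs are always computed on the full sample; the `trim` flag only marks
#' that plotting exports should drop the bottom and top 5% (a visual
#' device -- it never alters reported statistics).
#'
#' @param x Numeric sample (`length(x) >= 20`; NAs dropped with a warning).
#' @param trim Mark the summary for 5%/95% trimmed plotting exports.
#' @return One-row tibble: `median`, `q25`, `q75`, `p5`, `p95`, `n`,
#'   `trimmed`.
#' @examples
#' summarise_distribution(1:100)
#' @export
summarise_distribution <- function(x, trim = FALSE) {
  if (anyNA(x)) {
    warn(sprintf("Dropping %d NA value(s) before summarising.", sum(is.na(x))))
    x <- x[!is.na(x)]
  }
  if (length(x) < 20) abort("Need at least 20 samples to summarise a distribution.")
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  tibble::tibble(median = q[3], q25 = q[2], q75 = q[4], p5 = q[1], p95 = q[5],
                 n = length(x), trimmed = trim)
}

#' Drop the bottom and top 5% of a sample (plot exports only)
#' @param x Numeric sample.
#' @return The central 90% of `x`.
#' @export
trim_tails <- function(x) {
  q <- quantile(x, c(0.05, 0.95), names = FALSE, na.rm = TRUE)
  x[!is.na(x) & x >= q[1] & x <= q[2]]
}

#' Run the full techno-economic pipeline for one platform
#'
#' Orchestrates the whole chain deterministically: quasi-random scenario
#' design, production and cost KPIs, time to a dose target, capacity
#' projection with fill-to-finish, KPI distribution summaries, and
#' (optionally) the global sensitivity analysis. The run is reproducible
#' from its manifest: identical `(platform, n, skip, config)` give
#' byte-identical KPI tables.
#'
#' @param platform `"avv"`, `"mrna"` or `"sarna"`.
#' @param n Number of scenarios (the headline analyses use 10,000).
#' @param skip Sobol skip (default 1).
#' @param config A `vax_config`.
#' @param target Annual dose target for the projection (default 1e9).
#' @param fill_finish Fill-finish technology key (default: 10-dose vials
#'   for AVV, 5-dose vials for the RNA platforms), or `"none"`.
#' @param gsa Run the Sobol GSA as part of the pipeline (slower).
#' @param gsa_n Base sample count for the GSA design.
#' @return Object of class `vax_run`: list with `scenarios`, `kpis`
#'   (the per-scenario KPI table with time-to-target), `projection`,
#'   `summaries` (one row per summarised KPI), `sobol` (or `NULL`) and
#'   `manifest`.
#' @examples
#' run <- run_pipeline("sarna", n = 256)
#' glance(run)
#' @export
run_pipeline <- function(platform, n = 10000, skip = 1L,
                         config = vax_config(), target = 1e9,
                         fill_finish = NULL, gsa = FALSE, gsa_n = 1024) {
  platform <- match_platform(platform)
  fill_finish <- fill_finish %||% ifelse(platform == "avv", "vial10", "vial5")
  factors <- platform_factors(platform)
  cal <- platform_calibration(platform, config)
  ff <- fill_finish_spec(fill_finish, config)

  scenarios <- sample_scenarios(factors, n, skip = skip)
  kpis <- time_to_doses(simulate_kpis(scenarios, cal), target = target)
  projection <- project_resources(kpis, target = target, ff = ff)

  summary_cols <- c(
    doses_per_year = "kpis", specific_productivity = "kpis",
    time_to_target_years = "kpis", cost_per_dose = "kpis",
    opex_total = "kpis", capex = "kpis",
    required_scale = "projection", batches_per_year = "projection",
    capex_total = "projection")
  tabs <- list(kpis = kpis, projection = projection)
  summaries <- purrr::imap_dfr(summary_cols, function(tab, col) {
    dplyr::mutate(summarise_distribution(tabs[[tab]][[col]]),
                  kpi = col, table = tab, .before = 1)
  })

  sobol <- if (gsa) run_gsa(platform, n = gsa_n, config = config, skip = skip) else NULL

  manifest <- list(platform = platform, n = n, skip = skip, target = target,
                   fill_finish = fill_finish, gsa = gsa,
                   design_meta = attr(scenarios, "design_meta"),
                   config = unclass(config))
  out <- list(scenarios = scenarios, kpis = kpis, projection = projection,
              summaries = summaries, sobol = sobol, manifest = manifest)
  class(out) <- "vax_run"
  out
}

#' @export
print.vax_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<vax_run> %s, %d scenarios (skip %d), target %.3g doses/yr, fill-finish '%s'\n",
              m$platform, m$n, m$skip, m$target, m$fill_finish))
  print(x$summaries)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vax_run <- function(x, ...) x$summaries

#' @exportS3Method generics::glance
glance.vax_run <- function(x, ...) {
  med <- setNames(x$summaries$median, x$summaries$kpi)
  tibble::tibble(
    platform = x$manifest$platform,
    n = x$manifest$n,
    median_doses_per_year = med[["doses_per_year"]],
    median_specific_productivity = med[["specific_productivity"]],
    median_time_to_target_years = med[["time_to_target_years"]],
    median_cost_per_dose = med[["cost_per_dose"]],
    median_required_scale = med[["required_scale"]],
    median_capex_total = med[["capex_total"]]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.vax_run <- function(object, kpi = "time_to_target_years",
                             trim = TRUE, ...) {
  tab <- if (kpi %in% names(object$kpis)) object$kpis else object$projection
  if (!kpi %in% names(tab)) abort(sprintf("Unknown KPI '%s'.", kpi))
  x <- tab[[kpi]]
  if (trim) x <- trim_tails(x)
  df <- tibble::tibble(platform = object$manifest$platform, value = x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.08, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = kpi) +
    ggplot2::theme_minimal()
}

#' Compare KPI distributions across the three platforms
#'
#' Runs (or accepts) one pipeline per platform and draws trimmed violin
#' plots of a chosen KPI side by side.
#'
#' @param runs A named list of `vax_run` objects (names are platforms).
#' @param kpi KPI column to plot.
#' @param trim Drop the bottom/top 5% for display (statistics unaffected).
#' @return A ggplot object.
#' @export
plot_platform_comparison <- function(runs, kpi = "time_to_target_years",
                                     trim = TRUE) {
  df <- purrr::map_dfr(runs, function(r) {
    tab <- if (kpi %in% names(r$kpis)) r$kpis else r$projection
    x <- tab[[kpi]]
    if (trim) x <- trim_tails(x)
    tibble::tibble(platform = r$manifest$platform, value = x)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.08, outlier.shape = NA) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = kpi) +
    ggplot2::theme_minimal()
}
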