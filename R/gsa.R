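# Variance-based global sensitivity analysis. First-order (Si) and
# total-effect (St) Sobol indices are estimated with the Jansen (1999)
# estimators on a Saltelli A/B/AB design; confidence intervals by row
# bootstrap. An RS-HDMR polynomial metamodel (rshdmr.R) provides the
# surrogate-based route to the same indices.

#' Saltelli design for Sobol index estimation
#'
#' Builds the base matrices `A` and `B` (each `n x d` in the unit
#' hypercube) and the `d` cross matrices `AB_i` in which column `i` of `A`
#' is replaced by column `i` of `B`. Model evaluations required:
#' `n * (d + 2)`.
#'
#' Two constructions of the quasi-random blocks are supported:
#' * `"paired"` (default): one `2d`-dimensional Sobol sequence, columns
#'   split `A | B`. This is the standard construction; A and B are jointly
#'   low-discrepancy and uncorrelated.
#' * `"stream"`: `A` and `B` are consecutive disjoint blocks of one
#'   `d`-dimensional sequence. Kept for comparison; consecutive dyadic
#'   blocks of a digital net are structurally related, which can bias the
#'   estimators, so `"paired"` is preferred.
#'
#' @param n Base sample count (`n >= 2`).
#' @param d Dimension; or supply `factors` and leave `d` missing.
#' @param factors Optional factor set; design points are then mapped
#'   through the factor inverse CDFs and returned as scenario matrices.
#' @param skip Sobol skip (default 1).
#' @param method `"paired"` or `"stream"` (see above).
#' @return An object of class `vax_gsa_design`: list with `A`, `B`
#'   (`n x d`), `AB` (list of `d` matrices), `n`, `d`, `method`, `skip`,
#'   and if `factors` was given, the corresponding scenario-value matrices
#'   `A_x`, `B_x`, `AB_x`.
#' @examples
#' des <- saltelli_design(8, d = 3)
#' dim(des$A); length(des$AB)
#' @export
saltelli_design <- function(n, d = NULL, factors = NULL, skip = 1L,
                            method = c("paired", "stream")) {
  method <- match.arg(method)
  if (!is.null(factors)) {
    validate_factor_set(factors)
    d <- nrow(factors)
  }
  if (is.null(d)) abort("Supply `d` or `factors`.")
  if (n < 2) abort("`n` must be at least 2.")
  if (method == "paired") {
    U <- sobol_points(n, 2L * d, skip = skip)
    A <- U[, 1:d, drop = FALSE]
    B <- U[, (d + 1):(2 * d), drop = FALSE]
  } else {
    U <- sobol_points(2L * n, d, skip = skip)
    A <- U[seq_len(n), , drop = FALSE]
    B <- U[n + seq_len(n), , drop = FALSE]
  }
  AB <- purrr::map(seq_len(d), function(i) {
    M <- A
    M[, i] <- B[, i]
    M
  })
  des <- list(A = A, B = B, AB = AB, n = as.integer(n), d = as.integer(d),
              method = method, skip = as.integer(skip))
  if (!is.null(factors)) {
    des$factors <- factors
    des$A_x <- scenario_matrix(scenario_from_quantiles(factors, A))
    des$B_x <- scenario_matrix(scenario_from_quantiles(factors, B))
    des$AB_x <- purrr::map(AB, function(M)
      scenario_matrix(scenario_from_quantiles(factors, M)))
  }
  class(des) <- "vax_gsa_design"
  des
}

#' Evaluate a model over a Saltelli design
#'
#' @param design A `vax_gsa_design`.
#' @param f A function taking a matrix of design points (rows = points) and
#'   returning a numeric vector. Applied to the scenario-value matrices if
#'   the design carries a factor set, otherwise to the unit-cube matrices.
#' @return A list with `y_a`, `y_b` (length `n`) and `y_ab`
#'   (`n x d` matrix).
#' @export
evaluate_design <- function(design, f) {
  stopifnot(inherits(design, "vax_gsa_design"))
  use_x <- !is.null(design$A_x)
  A <- if (use_x) design$A_x else design$A
  B <- if (use_x) design$B_x else design$B
  ABs <- if (use_x) design$AB_x else design$AB
  list(
    y_a = f(A),
    y_b = f(B),
    y_ab = vapply(ABs, f, numeric(design$n))
  )
}

#' Sobol sensitivity indices from Saltelli-design model outputs
#'
#' Jansen estimators:
#' \deqn{S_i = 1 - \frac{\frac{1}{2n}\sum (y_B - y_{AB_i})^2}{V}}{Si = 1 - mean((yB - yABi)^2)/(2V)}
#' \deqn{S_{Ti} = \frac{\frac{1}{2n}\sum (y_A - y_{AB_i})^2}{V}}{St = mean((yA - yABi)^2)/(2V)}
#' with `V` the sample variance of the pooled `(y_A, y_B)` outputs.
#' Percentile bootstrap confidence intervals are obtained by resampling
#' design rows jointly across `y_A`, `y_B` and `y_AB`.
#'
#' Small negative `Si` estimates are legitimate estimator noise and are
#' \emph{not} clipped here; clip only for display.
#'
#' @param y_a,y_b Numeric vectors of model outputs over the `A` and `B`
#'   blocks.
#' @param y_ab Matrix (`n x d`) of outputs over the `AB_i` blocks.
#' @param n_boot Bootstrap resamples (default 1000; 0 disables CIs).
#' @param conf Confidence level for percentile intervals.
#' @param factor_names Optional names for the `d` factors.
#' @return A tibble of class `vax_sobol` with one row per factor: `factor`,
#'   `Si`, `St`, bootstrap `Si_sd`, `St_sd` and CI bounds `Si_lo`, `Si_hi`,
#'   `St_lo`, `St_hi`. If the output variance is zero the KPI is constant:
#'   indices are undefined, returned as NA with attribute
#'   `undefined = TRUE`.
#' @examples
#' des <- saltelli_design(256, d = 2)
#' f <- function(X) X[, 1] + 2 * X[, 2]
#' ys <- evaluate_design(des, f)
#' sobol_indices(ys$y_a, ys$y_b, ys$y_ab, n_boot = 100)
#' @export
sobol_indices <- function(y_a, y_b, y_ab, n_boot = 1000, conf = 0.95,
                          factor_names = NULL) {
  y_ab <- as.matrix(y_ab)
  n <- length(y_a)
  d <- ncol(y_ab)
  if (length(y_b) != n || nrow(y_ab) != n) {
    abort("`y_a`, `y_b` and rows of `y_ab` must have the same length.")
  }
  factor_names <- factor_names %||% colnames(y_ab) %||% paste0("x", seq_len(d))

  jansen <- function(ya, yb, yab) {
    V <- var(c(ya, yb))
    if (!is.finite(V) || V == 0) return(NULL)
    Si <- 1 - colMeans((yb - yab)^2) / (2 * V)
    St <- colMeans((ya - yab)^2) / (2 * V)
    rbind(Si, St)
  }

  est <- jansen(y_a, y_b, y_ab)
  if (is.null(est)) {
    warn("Model output is constant over the design; Sobol indices are undefined.")
    out <- tibble::tibble(factor = factor_names, Si = NA_real_, St = NA_real_,
                          Si_sd = NA_real_, St_sd = NA_real_,
                          Si_lo = NA_real_, Si_hi = NA_real_,
                          St_lo = NA_real_, St_hi = NA_real_)
    attr(out, "undefined") <- TRUE
    class(out) <- c("vax_sobol", class(out))
    return(out)
  }

  boot <- NULL
  if (n_boot > 0) {
    boot_si <- matrix(NA_real_, n_boot, d)
    boot_st <- matrix(NA_real_, n_boot, d)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bb <- jansen(y_a[idx], y_b[idx], y_ab[idx, , drop = FALSE])
      if (!is.null(bb)) {
        boot_si[b, ] <- bb["Si", ]
        boot_st[b, ] <- bb["St", ]
      }
    }
    alpha <- (1 - conf) / 2
    boot <- list(
      si_sd = apply(boot_si, 2, stats::sd, na.rm = TRUE),
      st_sd = apply(boot_st, 2, stats::sd, na.rm = TRUE),
      si_ci = apply(boot_si, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE),
      st_ci = apply(boot_st, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
    )
  }

  out <- tibble::tibble(
    factor = factor_names,
    Si = est["Si", ],
    St = est["St", ],
    Si_sd = if (is.null(boot)) NA_real_ else boot$si_sd,
    St_sd = if (is.null(boot)) NA_real_ else boot$st_sd,
    Si_lo = if (is.null(boot)) NA_real_ else boot$si_ci[1, ],
    Si_hi = if (is.null(boot)) NA_real_ else boot$si_ci[2, ],
    St_lo = if (is.null(boot)) NA_real_ else boot$st_ci[1, ],
    St_hi = if (is.null(boot)) NA_real_ else boot$st_ci[2, ]
  )
  attr(out, "n") <- n
  attr(out, "n_boot") <- n_boot
  attr(out, "undefined") <- FALSE
  class(out) <- c("vax_sobol", class(out))
  out
}

#' Interaction (additivity) gap per factor
#'
#' `St - Si` measures the variance share a factor contributes only through
#' interactions. For an additive model all gaps are zero up to estimator
#' noise; the techno-economic KPI chain is close to multiplicative in few
#' factors and shows only minor interactions.
#'
#' @param result A `vax_sobol` tibble (optionally with a `kpi` column).
#' @return The result with a `gap` column; attribute `max_gap` holds the
#'   largest gap (per KPI when a `kpi` column is present).
#' @export
additivity_gap <- function(result) {
  out <- dplyr::mutate(result, gap = .data$St - .data$Si)
  if ("kpi" %in% names(out)) {
    attr(out, "max_gap") <- dplyr::summarise(
      dplyr::group_by(out, .data$kpi), max_gap = max(.data$gap), .groups = "drop")
  } else {
    attr(out, "max_gap") <- max(out$gap)
  }
  out
}

#' Global sensitivity analysis of the techno-economic KPIs
#'
#' End-to-end GSA for one platform: builds a Saltelli design over the
#' platform's factor distributions, evaluates the production + cost model
#' on every design block and estimates Sobol indices of each input factor
#' on each KPI.
#'
#' @param platform `"avv"`, `"mrna"` or `"sarna"`.
#' @param n Base sample count (model evaluations: `n * (d + 2)`).
#' @param kpis KPI columns to analyse (default the eight headline KPIs).
#' @param config A `vax_config`.
#' @param n_boot Bootstrap resamples per KPI.
#' @param skip,method Passed to [saltelli_design()].
#' @return A `vax_sobol` tibble with a leading `kpi` column.
#' @examples
#' \donttest{
#' run_gsa("avv", n = 512, n_boot = 100)
#' }
#' @export
run_gsa <- function(platform, n = 1024,
                    kpis = c("capex", "opex_total", "batches_released_per_year",
                             "amount_per_batch", "amount_per_year",
                             "doses_per_batch", "doses_per_year", "cost_per_dose"),
                    config = vax_config(), n_boot = 200, skip = 1L,
                    method = "paired") {
  platform <- match_platform(platform)
  factors <- platform_factors(platform)
  cal <- platform_calibration(platform, config)
  des <- saltelli_design(n, factors = factors, skip = skip, method = method)

  eval_block <- function(U) {
    scen <- scenario_from_quantiles(factors, U)
    as.data.frame(simulate_kpis(scen, cal))[, kpis, drop = FALSE]
  }
  Y_a <- eval_block(des$A)
  Y_b <- eval_block(des$B)
  Y_ab <- purrr::map(des$AB, eval_block)

  res <- purrr::map_dfr(kpis, function(k) {
    yab <- vapply(Y_ab, function(df) df[[k]], numeric(n))
    r <- sobol_indices(Y_a[[k]], Y_b[[k]], yab, n_boot = n_boot,
                       factor_names = factors$name)
    dplyr::mutate(r, kpi = k, .before = 1)
  })
  attr(res, "platform") <- platform
  attr(res, "n") <- n
  class(res) <- c("vax_sobol", class(res))
  res
}

#' @exportS3Method generics::tidy
tidy.vax_sobol <- function(x, ...) {
  cols <- intersect(c("kpi", "factor", "Si", "St", "Si_lo", "Si_hi",
                      "St_lo", "St_hi"), names(x))
  out <- tibble::as_tibble(x)[, cols]
  tidyr::pivot_longer(out, cols = c("Si", "St"), names_to = "index",
                      values_to = "estimate")
}

#' @exportS3Method ggplot2::autoplot
autoplot.vax_sobol <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$estimate,
                                        fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "variance share",
                  title = "Sobol sensitivity indices") +
    ggplot2::theme_minimal()
  if ("kpi" %in% names(df)) p <- p + ggplot2::facet_wrap(~kpi)
  p
}
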