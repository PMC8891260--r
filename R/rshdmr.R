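# RS-HDMR metamodel: an additive expansion of a KPI in orthonormal
# (shifted Legendre) polynomials of each factor's unit-interval image,
#   f(x) ~ f0 + sum_i f_i(u_i),   f_i(u) = sum_k a_ik P_k(u),
# fitted by least squares on random/quasi-random samples. Because the basis
# is orthonormal on [0,1] and factors are independent, Var(f_i) = sum_k
# a_ik^2, so the fitted coefficients directly yield metamodel-based
# first-order sensitivity indices.

# orthonormal shifted Legendre polynomials on [0, 1], orders 1..3
shifted_legendre <- function(u, order) {
  switch(order,
    sqrt(3) * (2 * u - 1),
    sqrt(5) * (6 * u^2 - 6 * u + 1),
    sqrt(7) * (20 * u^3 - 30 * u^2 + 12 * u - 1),
    abort("Polynomial order must be 1, 2 or 3."))
}

rshdmr_basis <- function(u, max_order) {
  d <- ncol(u)
  cols <- purrr::map(seq_len(d), function(j) {
    m <- vapply(seq_len(max_order), function(k) shifted_legendre(u[, j], k),
                numeric(nrow(u)))
    colnames(m) <- paste0("f", j, "_p", seq_len(max_order))
    m
  })
  do.call(cbind, cols)
}

#' Fit an RS-HDMR polynomial metamodel
#'
#' Fits the additive component-function expansion (order up to 3 per
#' factor) to model outputs over a sampled design and derives
#' metamodel-based first-order sensitivity indices from the component
#' variances.
#'
#' @param u Design matrix in the unit hypercube (`n x d`), e.g. the Sobol
#'   points behind a scenario set; or a scenario tibble from
#'   [sample_scenarios()] whose factor values are mapped back to quantiles
#'   internally.
#' @param y Numeric response (one KPI per design row).
#' @param max_order Maximum polynomial order per factor (1--3).
#' @return An object of class `vax_rshdmr`: `f0` (the sample mean),
#'   `coefficients` (tidy tibble: factor, order, estimate), `Si`
#'   (metamodel first-order indices), `r_squared` (training), `max_order`,
#'   `d`, `n`.
#' @examples
#' u <- sobol_points(512, 2)
#' y <- u[, 1] + 2 * u[, 2]
#' fit <- fit_rshdmr(u, y)
#' glance(fit)
#' @export
fit_rshdmr <- function(u, y, max_order = 3) {
  u <- rshdmr_quantiles(u)
  n <- nrow(u)
  d <- ncol(u)
  p <- 1 + d * max_order
  if (n < 2 * p) abort("Too few design points for the requested expansion.")
  if (n < 10 * p) {
    warn(sprintf("Only %d points for %d coefficients (<10x); indices may be noisy.", n, p))
  }
  X <- rshdmr_basis(u, max_order)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1 || anyNA(fit$coefficients)) {
    abort("RS-HDMR design matrix is rank deficient; reduce `max_order` or add points.")
  }
  beta <- fit$coefficients[-1]
  names(beta) <- colnames(X)
  comp_var <- vapply(seq_len(d), function(j)
    sum(beta[((j - 1) * max_order + 1):(j * max_order)]^2), numeric(1))
  vy <- var(y)
  coefs <- tibble::tibble(
    factor = rep(seq_len(d), each = max_order),
    order = rep(seq_len(max_order), d),
    estimate = unname(beta))
  out <- list(
    f0 = unname(fit$coefficients[1]),
    coefficients = coefs,
    component_variance = comp_var,
    Si = comp_var / vy,
    r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
    var_y = vy,
    max_order = max_order,
    d = d,
    n = n)
  class(out) <- "vax_rshdmr"
  out
}

# accept either a unit-cube matrix or a scenario tibble
rshdmr_quantiles <- function(u) {
  if (inherits(u, "vax_scenarios")) {
    factors <- attr(u, "factor_set")
    X <- scenario_matrix(u)
    u <- vapply(seq_len(nrow(factors)), function(j) {
      f <- factors[j, ]
      if (f$dist == "triangular") ptriangular(X[, j], f$low, f$mode, f$high)
      else (X[, j] - f$low) / (f$high - f$low)
    }, numeric(nrow(X)))
  }
  u <- as.matrix(u)
  if (any(u < -1e-9 | u > 1 + 1e-9)) abort("Design points must lie in [0, 1].")
  pmin(pmax(u, 0), 1)
}

# triangular CDF (inverse of qtriangular)
ptriangular <- function(x, low, mode, high) {
  check_triangular(low, mode, high)
  lower <- (x - low)^2 / ((high - low) * (mode - low))
  upper <- 1 - (high - x)^2 / ((high - low) * (high - mode))
  out <- ifelse(x <= mode, lower, upper)
  pmin(pmax(out, 0), 1)
}

#' @export
predict.vax_rshdmr <- function(object, newdata, ...) {
  u <- rshdmr_quantiles(newdata)
  if (ncol(u) != object$d) abort("`newdata` has the wrong number of factors.")
  X <- rshdmr_basis(u, object$max_order)
  drop(object$f0 + X %*% object$coefficients$estimate)
}

#' Held-out validation R-squared of an RS-HDMR metamodel
#'
#' Coefficient of determination of the metamodel predictions on scenarios
#' never used for fitting -- the honest measure of whether the surrogate
#' can stand in for the full model.
#'
#' @param object A `vax_rshdmr` fit.
#' @param newdata Held-out design (unit-cube matrix or scenario tibble).
#' @param y Held-out responses.
#' @return R-squared (scalar).
#' @export
validate_rshdmr <- function(object, newdata, y) {
  pred <- predict(object, newdata)
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' @exportS3Method generics::tidy
tidy.vax_rshdmr <- function(x, ...) {
  tibble::tibble(factor = seq_len(x$d),
                 Si = x$Si,
                 component_variance = x$component_variance)
}

#' @exportS3Method generics::glance
glance.vax_rshdmr <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, f0 = x$f0, n = x$n, d = x$d,
                 max_order = x$max_order,
                 n_coefficients = 1 + x$d * x$max_order)
}

#' @export
print.vax_rshdmr <- function(x, ...) {
  cat(sprintf("<vax_rshdmr> %d factors, order <= %d, n = %d, training R^2 = %.4f\n",
              x$d, x$max_order, x$n, x$r_squared))
  invisible(x)
}
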