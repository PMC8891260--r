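#' Triangular distribution quantile function
#'
#' Inverse cumulative distribution function of the triangular distribution
#' with lower limit `low`, mode `mode` and upper limit `high`. Used to map
#' low-discrepancy points in \eqn{[0,1)} onto uncertain process factors that
#' have a highly probable central value.
#'
#' The closed form is
#' \deqn{Q(u) = low + \sqrt{u (high-low)(mode-low)}}{Q(u) = low + sqrt(u (high-low)(mode-low))}
#' for \eqn{u \le F(mode)} and
#' \deqn{Q(u) = high - \sqrt{(1-u)(high-low)(high-mode)}}{Q(u) = high - sqrt((1-u)(high-low)(high-mode))}
#' otherwise, where \eqn{F(mode) = (mode-low)/(high-low)}.
#'
#' @param u Probabilities in \eqn{[0, 1]} (vectorised).
#' @param low,mode,high Distribution parameters, `low <= mode <= high`,
#'   `low < high`. Degenerate `mode == low` or `mode == high` is allowed.
#' @return Quantiles, same length as `u`.
#' @examples
#' qtriangular(0.5, 3, 5, 7)        # symmetric: median equals mode
#' qtriangular(0.5, 1000, 2000, 20000)
#' @export
qtriangular <- function(u, low, mode, high) {
  check_triangular(low, mode, high)
  if (any(u < 0 | u > 1, na.rm = TRUE)) {
    abort("`u` must lie in [0, 1].")
  }
  fc <- (mode - low) / (high - low)
  lower <- low + sqrt(u * (high - low) * (mode - low))
  upper <- high - sqrt((1 - u) * (high - low) * (high - mode))
  ifelse(u < fc, lower, upper)
}

#' Triangular distribution random draws
#'
#' Pseudo-random draws by inversion; mostly useful for Monte Carlo
#' cross-checks of the quasi-random design.
#'
#' @param n Number of draws.
#' @inheritParams qtriangular
#' @return Numeric vector of length `n`.
#' @export
rtriangular <- function(n, low, mode, high) {
  qtriangular(runif(n), low, mode, high)
}

#' Uniform distribution quantile function
#'
#' Thin wrapper kept for symmetry with [qtriangular()]; factors whose value
#' is not well understood within their range (batch failure rate, QC cost
#' share) are modelled as uniform.
#'
#' @param u Probabilities in \eqn{[0, 1]}.
#' @param low,high Range limits, `low < high`.
#' @return Quantiles `low + u * (high - low)`.
#' @export
quniform <- function(u, low, high) {
  if (!(low < high)) abort("`low` must be strictly less than `high`.")
  if (any(u < 0 | u > 1, na.rm = TRUE)) abort("`u` must lie in [0, 1].")
  low + u * (high - low)
}

check_triangular <- function(low, mode, high) {
  if (!(low < high)) abort("Triangular parameters require `low < high`.")
  if (!(low <= mode && mode <= high)) {
    abort("Triangular parameters require `low <= mode <= high`.")
  }
  invisible(TRUE)
}

# closed-form mean of the triangular distribution, used in moment checks
triangular_mean <- function(low, mode, high) (low + mode + high) / 3
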