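#' Quasi-random scenario design for a platform
#'
#' The synthetic-data generator at the heart of the uncertainty analysis:
#' draws `n` scenarios from a platform's factor distributions by mapping a
#' Sobol low-discrepancy point set through each factor's inverse CDF
#' (triangular or uniform), column by column, preserving factor order.
#' The design is fully reproducible from its metadata (`n`, `skip`,
#' sequence type), recorded in the `"design_meta"` attribute.
#'
#' @param factors Factor set tibble from [platform_factors()].
#' @param n Number of scenarios.
#' @param skip Sobol sequence skip (default 1: drop the all-zeros point).
#' @param u Optional `n x d` matrix of quantiles in `[0,1]` to force
#'   specific design points instead of the Sobol sequence (used for
#'   deterministic probes and for Saltelli designs).
#' @return A scenario tibble: columns `platform`, `scenario` (row id) and
#'   one column per factor, in factor order; attributes `design_meta`
#'   (generator metadata) and `factor_set`.
#' @examples
#' fs <- platform_factors("mrna")
#' scen <- sample_scenarios(fs, n = 8)
#' scen
#' @export
sample_scenarios <- function(factors, n, skip = 1L, u = NULL) {
  validate_factor_set(factors)
  d <- nrow(factors)
  if (is.null(u)) {
    if (n < 1) abort("`n` must be at least 1.")
    u <- sobol_points(n, d, skip = skip)
    meta <- list(generator = "sobol", n = as.integer(n), d = d,
                 skip = as.integer(skip))
  } else {
    u <- as.matrix(u)
    if (ncol(u) != d) {
      abort(sprintf("`u` must have %d columns (one per factor).", d))
    }
    n <- nrow(u)
    meta <- list(generator = "forced", n = as.integer(n), d = d,
                 skip = NA_integer_)
  }
  scenario_from_quantiles(factors, u, meta = meta)
}

#' Map quantiles to factor values
#'
#' Lower-level constructor behind [sample_scenarios()]: applies each
#' factor's inverse CDF to one column of `u`.
#'
#' @inheritParams sample_scenarios
#' @param u Matrix of quantiles in `[0,1]`, one column per factor.
#' @param meta Optional metadata list recorded on the result.
#' @return A scenario tibble (see [sample_scenarios()]).
#' @export
scenario_from_quantiles <- function(factors, u, meta = NULL) {
  validate_factor_set(factors)
  u <- as.matrix(u)
  if (any(u < 0 | u > 1)) abort("Quantiles `u` must lie in [0, 1].")
  vals <- purrr::map(seq_len(nrow(factors)), function(j) {
    f <- factors[j, ]
    if (f$dist == "triangular") {
      qtriangular(u[, j], f$low, f$mode, f$high)
    } else {
      quniform(u[, j], f$low, f$high)
    }
  })
  names(vals) <- factors$name
  scen <- tibble::as_tibble(c(
    list(platform = factors$platform[1], scenario = seq_len(nrow(u))), vals))
  meta <- meta %||% list(generator = "forced", n = nrow(u), d = nrow(factors),
                         skip = NA_integer_)
  new_scenario_set(scen, factors, meta)
}

new_scenario_set <- function(scen, factors, meta) {
  attr(scen, "design_meta") <- meta
  attr(scen, "factor_set") <- factors
  class(scen) <- c("vax_scenarios", class(scen))
  scen
}

#' @export
print.vax_scenarios <- function(x, ...) {
  meta <- attr(x, "design_meta")
  cat(sprintf("<vax_scenarios> %s platform, %d scenario(s), generator=%s, skip=%s\n",
              x$platform[1], nrow(x), meta$generator %||% "?",
              as.character(meta$skip %||% NA)))
  NextMethod()
}

#' Extract factor columns of a scenario set as a matrix
#' @param scenarios Scenario tibble.
#' @return Numeric matrix, one column per factor in factor order.
#' @keywords internal
scenario_matrix <- function(scenarios) {
  factors <- attr(scenarios, "factor_set")
  as.matrix(scenarios[, factors$name])
}

#' Write / read a scenario design as CSV with a metadata header
#'
#' The CSV carries a `#`-prefixed header block (platform, generator, n,
#' skip) so a design can be reproduced or audited from the file alone.
#'
#' @param scenarios Scenario tibble from [sample_scenarios()].
#' @param path Output file path.
#' @return `path`, invisibly (`write_scenarios`); a scenario tibble
#'   (`read_scenarios` -- factor-set attribute is not restored).
#' @export
write_scenarios <- function(scenarios, path) {
  meta <- attr(scenarios, "design_meta") %||% list()
  hdr <- c(
    sprintf("# platform: %s", scenarios$platform[1]),
    sprintf("# generator: %s", meta$generator %||% "unknown"),
    sprintf("# n: %s", meta$n %||% nrow(scenarios)),
    sprintf("# skip: %s", meta$skip %||% NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(scenarios), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    meta[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
  }
  scen <- tibble::as_tibble(read.csv(text = paste(lines[-hdr], collapse = "\n")))
  attr(scen, "design_meta") <- meta
  scen
}
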