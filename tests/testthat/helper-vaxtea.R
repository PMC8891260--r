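# Shared fixtures: all built in code, no files.

# Ishigami benchmark on [0,1]^3 (inputs rescaled to [-pi, pi]) and its
# closed-form variance decomposition for a = 7, b = 0.1.
ishigami <- function(X) {
  x <- pi * (2 * X - 1)
  sin(x[, 1]) + 7 * sin(x[, 2])^2 + 0.1 * x[, 3]^4 * sin(x[, 1])
}

ishigami_indices <- local({
  a <- 7; b <- 0.1
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- 8 * b^2 * pi^8 / 225
  v <- v1 + v2 + v13
  list(Si = c(v1, v2, 0) / v,
       St = c(v1 + v13, v2, v13) / v)
})

# hand-built scenario row (bypasses the sampler) for deterministic probes
make_scenario <- function(platform, scale, titre, dose, failure = 5,
                          labour = 23, qc_share = 55, cap_price = 3000) {
  scen <- tibble::tibble(platform = platform, scenario = 1L,
                         scale = scale, failure = failure, titre = titre,
                         cap_price = cap_price, labour = labour,
                         dose = dose, qc_share = qc_share)
  if (platform == "avv") scen$cap_price <- NULL
  scen
}

# calibration with overridden scheduling constants
make_calibration <- function(platform, cycle_days, operating_days = 330,
                             lines = 1) {
  cal <- platform_calibration(platform)
  cal$batch_cycle_days <- cycle_days
  cal$operating_days <- operating_days
  cal$parallel_lines <- lines
  cal
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
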