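test_that("batch scheduling arithmetic", {
  expect_equal(batches_per_year(make_calibration("avv", 11)), 30)
  expect_equal(batches_per_year(make_calibration("avv", 330)), 1)
  expect_equal(batches_per_year(make_calibration("mrna", 1, lines = 2)), 660)
  cal <- make_calibration("mrna", 0)
  expect_error(batches_per_year(cal), "positive")
})

test_that("amount per batch is scale times net titre", {
  expect_equal(amount_per_batch(30, 5), 150)
  expect_equal(amount_per_batch(2000, 2.5e14), 5e17)
  expect_equal(amount_per_batch(123, 0), 0)
  expect_error(amount_per_batch(-1, 5), "non-negative")
})

test_that("annual output composes the KPI chain correctly", {
  # 30 L x 5 g/L = 150 g/batch; 30 ug/dose; 5% failure; 100 starts/yr
  scen <- make_scenario("mrna", scale = 30, titre = 5, dose = 30)
  cal <- make_calibration("mrna", cycle_days = 3.3)
  out <- simulate_production(scen, cal)
  expect_equal(out$batch_starts_per_year, 100)
  expect_equal(out$amount_per_batch, 150)
  expect_equal(out$doses_per_batch, 5e6)
  expect_equal(out$doses_per_year, 4.75e8)

  # total failure is a hard boundary
  dead <- simulate_production(make_scenario("mrna", 30, 5, 30, failure = 100), cal)
  expect_equal(dead$doses_per_year, 0)

  # platform mismatch is an error
  expect_error(simulate_production(scen, make_calibration("avv", 11)), "calibration")
})

test_that("production invariants hold across a sampled design", {
  for (p in c("avv", "mrna", "sarna")) {
    cal <- platform_calibration(p)
    scen <- sample_scenarios(platform_factors(p), 500)
    out <- simulate_production(scen, cal)
    conv <- if (p == "avv") 1 else 1e6
    # conservation: doses/yr x dose amount = amount/yr (in dose units)
    expect_equal(out$doses_per_year * out$dose, out$amount_per_year * conv)
    # brute-force oracle: straight-line recomputation of the KPI chain
    # (five multiplications/divisions), bit for bit
    starts <- cal$operating_days / cal$batch_cycle_days * cal$parallel_lines
    expect_identical(out$doses_per_year,
                     (scen$scale * scen$titre) *
                       (starts * (1 - scen$failure / 100)) * conv / scen$dose)
    expect_true(all(out$doses_per_year >= 0))
  }
})

test_that("output is linear in scale and monotone in the right directions", {
  cal <- make_calibration("mrna", 1)
  base <- simulate_production(make_scenario("mrna", 30, 5, 30), cal)
  dbl <- simulate_production(make_scenario("mrna", 60, 5, 30), cal)
  expect_equal(dbl$amount_per_batch, 2 * base$amount_per_batch)
  expect_equal(dbl$doses_per_year, 2 * base$doses_per_year)

  hi_titre <- simulate_production(make_scenario("mrna", 30, 6, 30), cal)
  hi_dose <- simulate_production(make_scenario("mrna", 30, 5, 40), cal)
  hi_fail <- simulate_production(make_scenario("mrna", 30, 5, 30, failure = 9), cal)
  expect_gt(hi_titre$doses_per_year, base$doses_per_year)
  expect_lt(hi_dose$doses_per_year, base$doses_per_year)
  expect_lt(hi_fail$doses_per_year, base$doses_per_year)
})

test_that("time to dose target is the reciprocal of annual output", {
  cal <- make_calibration("mrna", 3.3)
  out <- simulate_production(make_scenario("mrna", 30, 5, 30), cal)
  t1 <- time_to_doses(out, target = 1e9)
  expect_equal(t1$time_to_target_years, 1e9 / 4.75e8)
  expect_equal(time_to_doses(out, target = out$doses_per_year)$time_to_target_years, 1)
  # reciprocal identity over a design
  scen <- sample_scenarios(platform_factors("sarna"), 200)
  prod <- simulate_production(scen, platform_calibration("sarna"))
  tt <- time_to_doses(prod, 1e9)
  expect_equal(tt$time_to_target_years * tt$doses_per_year, rep(1e9, 200))
  # zero-output scenario flagged
  dead <- simulate_production(make_scenario("mrna", 30, 5, 30, failure = 100), cal)
  expect_warning(td <- time_to_doses(dead), "zero annual output")
  expect_true(td$undefined)
  expect_equal(td$time_to_target_years, Inf)
})
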