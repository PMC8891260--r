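ff_spec <- function(...) {
  spec <- list(technology = "test", doses_per_container = 1,
               containers_per_minute = 1, oee = 1, operating_minutes = 1,
               cost_per_container_usd = 0, capex_usd = 0,
               opex_fixed_usd_per_year = 0, capex_annualisation = 0.14,
               name = "test")
  spec[names(list(...))] <- list(...)
  class(spec) <- "vax_ff_spec"
  spec
}

test_that("fill-finish line throughput arithmetic", {
  # 10-dose vial line at 400 containers/min, OEE 60%, continuous operation
  vial10 <- fill_finish_spec("vial10")
  expect_equal(ff_annual_doses(vial10), 400 * 0.6 * 525600 * 10)
  expect_equal(ff_annual_doses(vial10) / 1e9, 1.26, tolerance = 0.01)
  # unit case
  expect_equal(ff_annual_doses(ff_spec()), 1)
  # linear in doses per container: 5-dose line fills half the doses
  vial5 <- fill_finish_spec("vial5")
  expect_equal(ff_annual_doses(vial5), ff_annual_doses(vial10) / 2)
})

test_that("bottleneck is the minimum of the stage rates, ties to DS", {
  b <- locate_bottleneck(5e8, 1.26e9)
  expect_equal(b$stage, "drug_substance")
  expect_equal(b$limiting_rate, 5e8)
  b2 <- locate_bottleneck(2e9, 1.26e9)
  expect_equal(b2$stage, "fill_finish")
  expect_equal(b2$limiting_rate, 1.26e9)
  expect_equal(locate_bottleneck(1e9, 1e9)$stage, "drug_substance")

  # a single 5-dose-vial line cannot keep up with baseline saRNA output
  sarna <- simulate_kpis(baseline_scenario("sarna"))
  b3 <- locate_bottleneck(sarna$doses_per_year,
                          ff_annual_doses(fill_finish_spec("vial5")))
  expect_equal(b3$stage, "fill_finish")
})

test_that("fill cost per dose accounting", {
  # container cost only: 0.50 USD vial, 10 doses
  only_vials <- ff_spec(doses_per_container = 10, cost_per_container_usd = 0.5)
  expect_equal(ff_cost_per_dose(only_vials), 0.05)
  # per-dose container cost halves when container capacity doubles
  bag100 <- ff_spec(doses_per_container = 100, cost_per_container_usd = 30)
  bag200 <- ff_spec(doses_per_container = 200, cost_per_container_usd = 30)
  expect_equal(ff_cost_per_dose(bag200), ff_cost_per_dose(bag100) / 2)
  # strictly decreasing in doses per container at fixed container cost
  costs <- vapply(c(1, 5, 10, 200), function(k)
    ff_cost_per_dose(ff_spec(doses_per_container = k, cost_per_container_usd = 1.5,
                             containers_per_minute = 400, oee = 0.6,
                             operating_minutes = 525600, capex_usd = 1e8)),
    numeric(1))
  expect_true(all(diff(costs) < 0))
  # zero-throughput line is flagged
  expect_warning(expect_true(is.na(ff_cost_per_dose(ff_spec(oee = 1e-300) |>
    (\(s) { s$operating_minutes <- 0; s })()))), "zero throughput")
})

test_that("unknown technologies and invalid OEE are rejected", {
  expect_error(fill_finish_spec("vial42"), "Unknown fill-finish")
  expect_null(fill_finish_spec("none"))
  cfg <- vax_config()
  cfg$fill_finish$vial5$oee <- 1.2
  expect_error(fill_finish_spec("vial5", cfg), "OEE")
})
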