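test_that("packaged factor sets encode the platform uncertainty model", {
  avv <- platform_factors("avv")
  mrna <- platform_factors("mrna")
  sarna <- platform_factors("sarna")

  # AVV has no cap-analogue factor; RNA platforms have seven factors
  expect_equal(nrow(avv), 6)
  expect_false("cap_price" %in% avv$name)
  expect_equal(nrow(mrna), 7)
  expect_equal(nrow(sarna), 7)

  # factor order is fixed (GSA indices are reported per position)
  expect_equal(mrna$name,
               c("scale", "failure", "titre", "cap_price", "labour", "dose", "qc_share"))
  expect_equal(avv$name, setdiff(mrna$name, "cap_price"))

  # the two uniform factors; all others triangular
  for (fs in list(avv, mrna, sarna)) {
    expect_equal(fs$name[fs$dist == "uniform"], c("failure", "qc_share"))
    expect_true(all(fs$low < fs$high))
    tri <- fs$dist == "triangular"
    expect_true(all(fs$low[tri] <= fs$mode[tri] & fs$mode[tri] <= fs$high[tri]))
  }

  # platform-specific ranges: saRNA's small dose, AVV's viral-particle units
  expect_equal(sarna[sarna$name == "dose", c("low", "mode", "high")],
               tibble::tibble(low = 0.1, mode = 1, high = 10))
  expect_equal(avv$mode[avv$name == "titre"], 2.5e14)
})

test_that("factor-set validation rejects malformed specs", {
  bad <- platform_factors("mrna")
  bad$low[1] <- bad$high[1] + 1
  expect_error(sample_scenarios(bad, 4), "low < high")
  bad2 <- platform_factors("mrna")
  bad2$mode[1] <- bad2$high[1] * 2
  expect_error(sample_scenarios(bad2, 4), "mode")
})

test_that("forced central quantiles recover symmetric central values", {
  fs <- platform_factors("mrna")
  scen <- sample_scenarios(fs, n = 1, u = matrix(0.5, 1, 7))
  expect_equal(scen$titre, 5)      # symmetric triangular: median = mode
  expect_equal(scen$failure, 5)    # uniform midpoint
  expect_equal(scen$qc_share, 55)
  # labour (5, 23, 30) is skewed; median sits below the mode
  expect_lt(scen$labour, 23)
})

test_that("baseline scenarios sit at the central factor values", {
  avv <- baseline_scenario("avv")
  expect_equal(avv$scale, 2000)
  expect_equal(avv$titre, 2.5e14)
  expect_equal(avv$dose, 5e10)
  expect_equal(avv$failure, 7.5)
  expect_equal(avv$labour, 23)
  mrna <- baseline_scenario("mrna")
  expect_equal(mrna$scale, 30)
  expect_equal(mrna$dose, 30)
  expect_equal(mrna$cap_price, 3000)
})

test_that("sampled designs respect factor bounds and are reproducible", {
  for (p in c("avv", "mrna", "sarna")) {
    fs <- platform_factors(p)
    scen <- sample_scenarios(fs, n = 2000)
    for (j in seq_len(nrow(fs))) {
      v <- scen[[fs$name[j]]]
      expect_true(all(v >= fs$low[j] & v <= fs$high[j]),
                  label = paste(p, fs$name[j], "within bounds"))
    }
  }
  fs <- platform_factors("sarna")
  a <- sample_scenarios(fs, 512, skip = 1)
  b <- sample_scenarios(fs, 512, skip = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # different skip gives a different (but still in-bounds) design
  c_ <- sample_scenarios(fs, 512, skip = 5)
  expect_false(identical(a$scale, c_$scale))
})

test_that("scenario CSV round-trips with its metadata header", {
  fs <- platform_factors("avv")
  scen <- sample_scenarios(fs, 32, skip = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenarios(scen, path)
  back <- read_scenarios(path)
  expect_equal(as.data.frame(back), as.data.frame(scen), ignore_attr = TRUE)
  meta <- attr(back, "design_meta")
  expect_equal(meta$platform, "avv")
  expect_equal(meta$n, 32)
  expect_equal(meta$skip, 3)
  expect_equal(meta$generator, "sobol")
})
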