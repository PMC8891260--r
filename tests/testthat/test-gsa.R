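test_that("Saltelli design structure", {
  des <- saltelli_design(8, d = 3)
  expect_equal(dim(des$A), c(8, 3))
  expect_equal(dim(des$B), c(8, 3))
  expect_length(des$AB, 3)
  # n x (d + 2) = 40 model evaluations in total
  expect_equal(des$n * (des$d + 2), 40)
  # AB_1 differs from A only in column 1
  expect_equal(des$AB[[1]][, -1], des$A[, -1])
  expect_equal(des$AB[[1]][, 1], des$B[, 1])
  # paired method: A|B are the split columns of one 2d-dimensional sequence
  U <- sobol_points(8, 6, skip = 1)
  expect_equal(des$A, U[, 1:3])
  expect_equal(des$B, U[, 4:6])
  # stream method: A and B are disjoint consecutive blocks of one stream
  des_s <- saltelli_design(8, d = 3, method = "stream")
  V <- sobol_points(16, 3, skip = 1)
  expect_equal(des_s$A, V[1:8, ])
  expect_equal(des_s$B, V[9:16, ])
})

test_that("additive linear model recovers exact variance shares", {
  # Y = X1 + 2 X2 on U(0,1)^2: Var = 1/12 + 4/12, S1 = 0.2, S2 = 0.8
  des <- saltelli_design(2^11, d = 2)
  ys <- evaluate_design(des, function(X) X[, 1] + 2 * X[, 2])
  set.seed(11)
  res <- sobol_indices(ys$y_a, ys$y_b, ys$y_ab, n_boot = 500)
  expect_equal(res$Si, c(0.2, 0.8), tolerance = 0.02)
  expect_equal(res$St, c(0.2, 0.8), tolerance = 0.02)
  # additive: total equals first-order within estimator noise
  gaps <- additivity_gap(res)
  expect_lt(max(abs(gaps$gap)), 0.02)
})

test_that("Ishigami interaction structure is resolved", {
  des <- saltelli_design(2^12, d = 3)
  ys <- evaluate_design(des, ishigami)
  set.seed(12)
  res <- sobol_indices(ys$y_a, ys$y_b, ys$y_ab, n_boot = 300)
  expect_equal(res$Si, ishigami_indices$Si, tolerance = 0.03)
  expect_equal(res$St, ishigami_indices$St, tolerance = 0.03)
  # X3 acts only through its interaction with X1
  gaps <- additivity_gap(res)
  expect_equal(gaps$gap[3], ishigami_indices$St[3], tolerance = 0.03)
  expect_lt(abs(gaps$gap[2]), 0.03)
})

test_that("constant output is flagged undefined", {
  des <- saltelli_design(64, d = 2)
  ys <- evaluate_design(des, function(X) rep(3, nrow(X)))
  expect_warning(res <- sobol_indices(ys$y_a, ys$y_b, ys$y_ab, n_boot = 0),
                 "constant")
  expect_true(attr(res, "undefined"))
  expect_true(all(is.na(res$Si)))
})

test_that("platform GSA reproduces the headline factor rankings", {
  set.seed(2)
  si_for <- function(platform, kpi) {
    g <- run_gsa(platform, n = 1024, kpis = kpi, n_boot = 0)
    setNames(g$Si, g$factor)
  }
  # AVV annual doses: scale, then titre, then dose amount
  avv <- si_for("avv", "doses_per_year")
  expect_gte(avv[["scale"]], avv[["titre"]])
  expect_gte(avv[["titre"]], avv[["dose"]])
  # RNA platforms: amount per dose dominates, then production scale
  for (p in c("mrna", "sarna")) {
    rna <- si_for(p, "doses_per_year")
    expect_gt(rna[["dose"]], rna[["scale"]])
    expect_gt(rna[["scale"]], max(rna[c("failure", "labour", "qc_share")]))
  }
})

test_that("techno-economic KPI effects are predominantly additive", {
  g <- run_gsa("mrna", n = 2048,
               kpis = c("doses_per_year", "cost_per_dose"), n_boot = 0)
  gaps <- additivity_gap(g)
  # first-order effects carry most of the variance of every KPI; the
  # residual interaction share comes from the multiplicative scale x dose
  # structure of the annual-amount KPIs (see the methods vignette)
  sums <- tapply(g$Si, g$kpi, sum)
  expect_true(all(sums > 0.7))
  expect_lt(max(gaps$gap), 0.2)
  # cost per dose is essentially one-factor additive
  expect_lt(max(gaps$gap[gaps$kpi == "cost_per_dose"]), 0.02)
})
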