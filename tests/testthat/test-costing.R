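test_that("unit-cost curve anchors: origin, marginal cost, saturation", {
  cf <- cost_function(unit_cost = 0.35, target_pop_size = 1e6,
                      saturation = 0.95)
  expect_equal(coverage_from_spending(cf, 0), 0)
  # marginal cost at low coverage is the unit cost: slope 1/(P u) at S -> 0
  eps <- 1
  slope <- coverage_from_spending(cf, eps) / eps * cf$target_pop_size
  expect_equal(slope, 1 / 0.35, tolerance = 1e-3)
  # linear regime: $3,500 on a $0.35 program covering 1e6 people ~ 1%
  expect_lt(abs(coverage_from_spending(cf, 3500) - 0.009999), 1e-5)
  # asymptote
  big <- 20 * cf$saturation * cf$target_pop_size * cf$unit_cost
  expect_equal(coverage_from_spending(cf, big), 0.95, tolerance = 1e-6)
  expect_error(coverage_from_spending(cf, -1), "non-negative")
})

test_that("spending_from_coverage is the exact inverse", {
  cf <- cost_function(3.56, 4.5e6, 0.95)
  expect_equal(spending_from_coverage(cf, 0), 0)
  s <- c(1e4, 1e6, 5e6, 2e7)
  expect_equal(spending_from_coverage(cf, coverage_from_spending(cf, s)), s,
               tolerance = 1e-9)
  expect_equal(spending_from_coverage(cf, cf$saturation / 2),
               cf$saturation * cf$target_pop_size * cf$unit_cost * atanh(0.5))
  expect_error(spending_from_coverage(cf, 0.95), "unreachable")
})

test_that("coverage is increasing in spending with diminishing returns", {
  cf <- cost_function(1.8, 3e6, 0.9)
  s <- seq(0, 4e7, length.out = 200)
  cv <- coverage_from_spending(cf, s)
  expect_true(all(diff(cv) > 0))
  expect_true(all(diff(diff(cv)) < 1e-12))
})

test_that("current-spending arithmetic reproduces the published table", {
  # $3.56 x 4.017 million beneficiaries ~ $14.3 m
  expect_equal(estimate_current_spending(3.56, 14.3e6 / 3.56) / 1e6, 14.3)
  expect_equal(estimate_current_spending(3.56, 0), 0)
  db <- demo_db()
  sp <- baseline_spending(db)
  expect_equal(unname(sp[c("AMS", "BEP", "CFS")]), c(0, 0, 0))
  expect_equal(unname(sp[["BFP"]]) / 1e6, 14.3, tolerance = 1e-9)
  expect_equal(unname(sp[["IYCF"]]) / 1e6, 4.1, tolerance = 1e-9)
  expect_equal(unname(sp[["VAS"]]) / 1e6, 3.8, tolerance = 1e-9)
})

test_that("allocation shares reproduce the published percentages", {
  alloc <- c(BFP = 14.3, IYCF = 4.1, VAS = 3.8)
  sh <- allocation_shares(alloc, percent_digits = 0)
  expect_equal(unname(sh[["BFP"]]), 64)
  expect_equal(unname(sh[["VAS"]]), 17)
  # the IYCF share from these inputs is 18.5%, not the printed 19
  expect_equal(unname(allocation_shares(alloc, 1)[["IYCF"]]), 18.5)
  expect_equal(unname(allocation_shares(c(x = 5), 0)), 100)
  expect_error(allocation_shares(c(a = 0, b = 0)), "positive")
})

test_that("fitted logistic recovers known parameters", {
  truth <- list(L = 0.9, k = 1.2e-6, S0 = 2e6)
  s <- seq(1e5, 6e6, length.out = 15)
  cv <- truth$L / (1 + exp(-truth$k * (s - truth$S0)))
  cf <- fit_cost_function(data.frame(spending = s, coverage = cv))
  expect_equal(cf$L, truth$L, tolerance = 1e-6)
  expect_equal(cf$k, truth$k, tolerance = 1e-6)
  expect_equal(cf$S0, truth$S0, tolerance = 1e-2)
  expect_lt(cf$residual_norm, 1e-8)
  # with noise, recovery within a noise-scaled tolerance
  set.seed(42)
  noisy <- cv + rnorm(length(cv), sd = 0.005)
  cf2 <- fit_cost_function(data.frame(spending = s, coverage = noisy))
  expect_equal(cf2$L, truth$L, tolerance = 0.05)
  expect_equal(cf2$S0, truth$S0, tolerance = 0.05)
  expect_error(
    fit_cost_function(data.frame(spending = s[1:2], coverage = cv[1:2])),
    "at least 3")
  expect_error(
    fit_cost_function(data.frame(spending = rep(1e5, 5),
                                 coverage = rep(0.2, 5))),
    "degenerate")
})

test_that("target populations follow the databook rules", {
  db <- demo_db()
  yr <- as.character(db$horizon$start_year)
  expect_equal(target_population_size(db, "AMS"),
               db$demographics$annual_births[[yr]])
  expect_equal(target_population_size(db, "BEP"),
               db$demographics$annual_births[[yr]] *
                 db$demographics$poverty_fraction)
  expect_equal(target_population_size(db, "CFS"),
               sum(db$demographics$population_per_band[c("6-11m", "12-23m")]) *
                 db$demographics$poverty_fraction)
  # explicit denominators override the rule
  expect_equal(target_population_size(db, "VAS"), 3.8e6 / (0.35 * 0.621))
  expect_error(target_population_size(db, "XYZ"), "unknown")
})
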