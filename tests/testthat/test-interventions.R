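ef <- default_effect_sizes()

test_that("antenatal programs shift birth outcomes on the odds scale", {
  base <- setNames(c(0.6, 0.2, 0.15, 0.05), birth_outcomes())
  expect_equal(birth_outcome_effect(0, 0, 0.3, base, ef), base)
  # no below-poverty pregnancies: BEP is inert at any coverage
  expect_equal(birth_outcome_effect(0, 1, 0, base, ef), base)
  # full AMS coverage with OR 0.5 on a 0.2 SGA fraction: odds 0.25 -> 0.125
  ef2 <- ef
  ef2$program_effects$ams_birth_or <- 0.5
  base2 <- setNames(c(0.8, 0.2, 0, 0), birth_outcomes())
  out <- birth_outcome_effect(1, 0, 0.3, base2, ef2)
  expect_equal(unname(out[["term_sga"]]), 0.125 / 1.125, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("breastfeeding promotion moves exclusive prevalence linearly", {
  base <- setNames(c(0.61, 0.20, 0.13, 0.06), breastfeeding_categories())
  # anchor point: coverage at baseline leaves the distribution unchanged
  expect_equal(breastfeeding_shift(0.61, base, "<1m", 0.61, ef), base)
  # full coverage attains the ceiling, others rescaled proportionally
  out <- breastfeeding_shift(1, base, "<1m", 0.61, ef)
  expect_equal(unname(out[["exclusive"]]), 0.9)
  expect_equal(unname(out[c("predominant", "partial", "none")]),
               unname(base[c("predominant", "partial", "none")] * 0.1 / 0.39),
               tolerance = 1e-12)
  # distribution stays a probability vector everywhere on the coverage range
  for (cv in seq(0, 1, by = 0.1)) {
    d <- breastfeeding_shift(cv, base, "1-5m", 0.61, ef)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
  }
  # bands of 6 months and older are untouched
  expect_equal(breastfeeding_shift(1, base, "12-23m", 0.61, ef), base)
})

test_that("feeding-program stunting multiplier respects the poverty split", {
  expect_equal(stunting_program_or(0, 0, 0.3, "6-11m", ef), 1)
  # education alone cannot help the food-insecure
  expect_equal(stunting_program_or(1, 0, 1, "6-11m", ef), 1)
  ef2 <- ef
  ef2$program_effects$iycf_stunting_or <- 0.7
  expect_equal(stunting_program_or(1, 0, 0, "12-23m", ef2), 0.7)
  # outside 6-23 months there is no effect
  expect_equal(stunting_program_or(1, 1, 0.3, "24-59m", ef), 1)
  # population average mixes the two strata
  q <- 0.4
  got <- stunting_program_or(0.5, 0.5, q, "6-11m", ef)
  pe <- ef$program_effects
  expect_equal(got,
               (1 - q) * (1 - 0.5 * (1 - pe$iycf_stunting_or)) +
                 q * (1 - 0.5 * (1 - pe$cfs_stunting_or)))
})

test_that("mortality multipliers follow the program target rules", {
  cov0 <- coverage_vector()
  for (b in age_bands()) {
    for (cz in causes_of_death(b)) {
      expect_equal(mortality_program_rr(cov0, b, cz, ef), 1)
    }
  }
  ef2 <- ef
  ef2$program_effects$vas_diarrhea_mortality_reduction <- 0.3
  cov <- coverage_vector(VAS = 0.621)
  expect_equal(mortality_program_rr(cov, "6-11m", "diarrhea", ef2), 0.8137)
  # vitamin A does not reach the under-6-month bands
  expect_equal(mortality_program_rr(cov, "<1m", "diarrhea", ef2), 1)
  expect_equal(mortality_program_rr(cov, "1-5m", "diarrhea", ef2), 1)
  # and does not touch other causes
  expect_equal(mortality_program_rr(cov, "12-23m", "pneumonia", ef2), 1)
})

test_that("intervention effects are monotone and bounded in coverage", {
  base_bf <- setNames(c(0.5, 0.2, 0.2, 0.1), breastfeeding_categories())
  base_out <- setNames(c(0.55, 0.28, 0.12, 0.05), birth_outcomes())
  grid <- seq(0, 1, by = 0.05)
  sga <- vapply(grid, function(cv) {
    o <- birth_outcome_effect(cv, cv, 0.3, base_out, ef)
    o[["term_sga"]] + o[["preterm_sga"]]
  }, 0)
  expect_true(all(diff(sga) <= 1e-12))
  excl <- vapply(grid, function(cv) {
    breastfeeding_shift(cv, base_bf, "<1m", 0.3, ef)[["exclusive"]]
  }, 0)
  expect_true(all(diff(excl) >= -1e-12))
  or <- vapply(grid, function(cv) {
    stunting_program_or(cv, cv, 0.3, "6-11m", ef)
  }, 0)
  expect_true(all(diff(or) <= 1e-12))
  expect_true(all(or > 0 & or <= 1))
  mr <- vapply(grid, function(cv) {
    mortality_program_rr(coverage_vector(VAS = cv, IYCF = cv), "12-23m",
                         "diarrhea", ef)
  }, 0)
  expect_true(all(diff(mr) <= 1e-12))
  expect_true(all(mr > 0 & mr <= 1))
})

test_that("zero coverage reproduces the unmodified baseline model", {
  db <- toy_databook()  # all baseline coverages zero
  params <- calibrate(db, verbose = FALSE)
  zero <- coverage_vector()
  e1 <- nutriopt:::build_engine(params, zero)
  e2 <- nutriopt:::build_engine(params, baseline_coverage_vector(db))
  expect_identical(e1, e2)
  t1 <- run_projection(db, params, zero, months = 24)
  t2 <- run_projection(db, params, zero, months = 24)
  expect_identical(t1$summary, t2$summary)
  # rates carry no program factor at zero coverage
  r <- mortality_rates(params, zero)
  rr <- mortality_rates(params, coverage_vector(VAS = 0.5))
  expect_lt(max(abs(r[["6-11m"]][, "diarrhea"] -
                      rr[["6-11m"]][, "diarrhea"] /
                        (1 - 0.5 * ef$program_effects$vas_diarrhea_mortality_reduction))),
            1e-15)
})
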