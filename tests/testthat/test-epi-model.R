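test_that("initialization distributes bands over strata by the product rule", {
  db <- toy_databook()
  db$risks$stunting_distribution["<1m", ] <- c(0.5, 0.2, 0.2, 0.1)
  db$risks$breastfeeding_distribution["<1m", ] <- c(1, 0, 0, 0)
  db$demographics$population_per_band[["<1m"]] <- 100
  st <- initialize_state(db)
  expect_equal(unname(st$counts[1, 1]), 50)  # (normal, exclusive)
  expect_equal(colSums(st$counts),
               db$demographics$population_per_band)
  expect_equal(st$cumulative$deaths_total, 0)
  # the demo fixture initializes at the published aggregate prevalence
  st2 <- initialize_state(demo_db())
  expect_equal(sum(st2$counts[nutriopt:::stunted_mask(), ]) / sum(st2$counts),
               0.36, tolerance = 0.005)
})

test_that("closed-form hazard solvers match their defining identities", {
  # a single band of width one month occupied for 60 months: the monthly
  # rate solves 1 - (1 - m)^60 = U5MR/1000
  m <- monthly_hazard_for_total(46 / 1000, 60)
  expect_equal(1 - (1 - m)^60, 46 / 1000, tolerance = 1e-12)
  # band-advance probability against brute-force month iteration
  mu <- 0.01; w <- 6
  alive <- 1; advanced <- 0
  for (k in 1:10000) {
    alive <- alive * (1 - mu)
    advanced <- advanced + alive / w
    alive <- alive * (1 - 1 / w)
  }
  expect_equal(band_advance_probability(mu, w), advanced, tolerance = 1e-12)
})

test_that("calibration closes the loop on mortality and stunting", {
  db <- demo_db()
  params <- demo_params()
  d <- params$diagnostics
  expect_equal(d$u5mr_simulated, 46, tolerance = 46 * 0.005)
  expect_equal(d$neonatal_share_simulated, 0.5, tolerance = 0.01)
  expect_lt(d$max_entry_stunting_error, 0.005)
  # the "other" cause absorbs a non-negative residual
  expect_true(all(params$m >= 0))
})

test_that("a single named cause receives all deaths", {
  db <- toy_databook(
    cause_neo = setNames(c(1, 0, 0, 0, 0, 0, 0), causes_of_death("<1m")),
    cause_post = setNames(c(1, 0, 0, 0), causes_of_death("1-5m")))
  params <- calibrate(db, verbose = FALSE)
  flows <- nutriopt:::cohort_flows(
    nutriopt:::build_engine(params, baseline_coverage_vector(db)))
  dc <- flows$deaths_by_cause
  expect_equal(dc[["diarrhea"]] / sum(dc), 1, tolerance = 1e-9)
})

test_that("relative risks redistribute but never create mortality", {
  params <- demo_params()
  cov0 <- coverage_vector()
  rates <- mortality_rates(params, cov0)
  for (band in age_bands()) {
    ws <- params$baseline$stunting_distribution[band, ]
    wb <- params$baseline$breastfeeding_distribution[band, ]
    w16 <- as.vector(outer(ws, wb))
    for (cz in causes_of_death(band)) {
      expect_equal(sum(w16 * rates[[band]][, cz]), params$m[band, cz],
                   tolerance = 1e-12 + 1e-12 * params$m[band, cz])
    }
  }
  # neutral effects: every stratum gets exactly the band rate
  dbn <- toy_databook(effects = neutral_effect_sizes())
  pn <- calibrate(dbn, verbose = FALSE)
  rn <- mortality_rates(pn, cov0)
  for (band in age_bands()) {
    for (cz in causes_of_death(band)) {
      expect_equal(max(abs(rn[[band]][, cz] - pn$m[band, cz])), 0,
                   tolerance = 1e-15)
    }
  }
})

test_that("a 2x2 relative-risk toy normalizes as enumerated by hand", {
  # two effective stunting levels (1, 2) and two breastfeeding levels
  # (1, 3) with uniform weights: Z = 1.5 * 2 = 3 and the (severe, none)
  # stratum gets rate 2m
  ef <- neutral_effect_sizes()
  ef$stunting_mortality_rr$diarrhea <-
    setNames(c(1, 1, 2, 2), stunting_categories())
  ef$bf_mortality_rr[["6-11m"]]$diarrhea <-
    setNames(c(1, 1, 3, 3), breastfeeding_categories())
  unif <- matrix(0.25, 5, 4,
                 dimnames = list(age_bands(), stunting_categories()))
  db <- toy_databook(effects = ef, stunting = unif)
  params <- calibrate(db, verbose = FALSE)
  expect_equal(params$Z["6-11m", "diarrhea"], 3, tolerance = 1e-12)
  r <- mortality_rates(params, coverage_vector())[["6-11m"]][, "diarrhea"]
  m <- params$m["6-11m", "diarrhea"]
  expect_equal(r[[16]], 2 * m, tolerance = 1e-12)  # severe x none
  expect_equal(r[[1]], m / 3, tolerance = 1e-12)   # normal x exclusive
})

test_that("the mortality operator satisfies the (1-mu)^w closed form", {
  db <- toy_databook(effects = neutral_effect_sizes())
  params <- calibrate(db, verbose = FALSE)
  mu <- 0.013
  params$m[] <- 0
  params$m["24-59m", "other"] <- mu
  engine <- nutriopt:::build_engine(params, coverage_vector())
  engine$widths <- rep(Inf, 5)  # isolate mortality: no aging outflow
  counts <- matrix(0, 16, 5)
  counts[, 5] <- 1000 / 16
  w <- 36
  for (k in seq_len(w)) {
    counts <- nutriopt:::step_core(counts, engine, 0)$counts
  }
  expect_equal(sum(counts), 1000 * (1 - mu)^w, tolerance = 1e-12)
})

test_that("band pass-through and one-month survival behave exactly", {
  # width-1 band with monthly mortality 0.1: of 1000 entrants, 900 leave
  # the band alive after one month
  db <- toy_databook(effects = neutral_effect_sizes())
  params <- calibrate(db, verbose = FALSE)
  params$m[] <- 0
  params$m["<1m", "other"] <- 0.1
  engine <- nutriopt:::build_engine(params, coverage_vector())
  counts <- matrix(0, 16, 5)
  res <- nutriopt:::step_core(counts, engine, 1000)
  expect_equal(sum(vapply(res$deaths_by_cause, sum, 0)), 100,
               tolerance = 1e-9)
  expect_equal(sum(res$counts[, 1]), 0, tolerance = 1e-9)
  expect_equal(sum(res$counts[, 2]), 900, tolerance = 1e-9)
})

test_that("with no mortality and no births everyone eventually graduates", {
  db <- toy_databook(effects = neutral_effect_sizes())
  params <- calibrate(db, verbose = FALSE)
  params$m[] <- 0
  st <- initialize_state(db)
  total0 <- sum(st$counts)
  cov <- coverage_vector()
  for (k in seq_len(1200)) st <- step_month(st, params, cov, 0)
  expect_equal(st$cumulative$graduates_total, total0,
               tolerance = 1e-9 * total0)
  expect_lt(sum(st$counts), 1e-6 * total0)
  expect_equal(st$cumulative$deaths_total, 0)
})

test_that("the person ledger balances every month on random fixtures", {
  set.seed(11)
  for (rep in 1:4) {
    db <- random_databook()
    params <- calibrate(db, verbose = FALSE)
    cov <- baseline_coverage_vector(db)
    st <- initialize_state(db)
    for (k in seq_len(24)) {
      before <- sum(st$counts)
      cum0 <- st$cumulative
      st <- step_month(st, params, cov, 1000)
      delta <- sum(st$counts) - before
      flows <- 1000 - (st$cumulative$deaths_total - cum0$deaths_total) -
        (st$cumulative$graduates_total - cum0$graduates_total)
      expect_equal(delta, flows, tolerance = 1e-9 * max(before, 1))
      expect_true(all(st$counts >= 0))
      expect_lte(st$cumulative$graduates_not_stunted,
                 st$cumulative$graduates_total + 1e-12)
    }
  }
})

test_that("age transitions conserve counts and follow odds arithmetic", {
  db <- toy_databook(effects = neutral_effect_sizes())
  params <- calibrate(db, verbose = FALSE)
  cov <- coverage_vector()
  out <- runif(16, 0, 100)
  moved <- age_transition(out, params, cov, "6-11m", "12-23m")
  expect_equal(sum(moved), sum(out), tolerance = 1e-12 * sum(out))
  # neutral effects: arrivals take the target band's baseline distribution
  joint <- as.vector(outer(params$baseline$stunting_distribution["12-23m", ],
                           params$baseline$breastfeeding_distribution["12-23m", ]))
  expect_equal(moved / sum(moved), joint, tolerance = 1e-9)
  # prior-stunting odds ratio 2 on entry odds 0.25: stunted children face
  # odds 0.5, i.e. probability 1/3
  ef <- neutral_effect_sizes()
  ef$stunting_or_prev <- 2
  db2 <- toy_databook(effects = ef)
  p2 <- calibrate(db2, verbose = FALSE)
  p2$entry_odds[["12-23m"]] <- 0.25
  pr <- nutriopt:::transition_stunted_prob(p2, cov, 3)
  expect_equal(unname(pr[3]), 1 / 3, tolerance = 1e-12)  # was stunted
  expect_equal(unname(pr[1]), 0.2, tolerance = 1e-12)    # odds 0.25
})

test_that("diarrhea incidence responds to breastfeeding and vitamin A", {
  params <- demo_params()
  covA <- coverage_vector(VAS = 1)
  ef <- params$baseline$effects
  red <- ef$program_effects$vas_diarrhea_incidence_reduction
  inc0 <- diarrhea_incidence(params, coverage_vector(), "6-11m")
  incA <- diarrhea_incidence(params, covA, "6-11m")
  expect_equal(incA, inc0 * (1 - red), tolerance = 1e-12)
  # under 6 months vitamin A has no effect
  expect_equal(diarrhea_incidence(params, covA, "1-5m"),
               diarrhea_incidence(params, coverage_vector(), "1-5m"))
  # the baseline-distribution-weighted mean equals the baseline incidence
  wb <- params$baseline$breastfeeding_distribution["6-11m", ]
  expect_equal(sum(wb * inc0),
               params$baseline$diarrhea_incidence[["6-11m"]],
               tolerance = 1e-12)
  # the age-appropriate reference category accrues zero excess episodes
  exc <- excess_diarrhea_episodes(params, coverage_vector(), "6-11m")
  expect_equal(unname(exc[["partial"]]), 0)
  exc2 <- excess_diarrhea_episodes(params, coverage_vector(), "<1m")
  expect_equal(unname(exc2[["exclusive"]]), 0)
  expect_true(all(exc >= 0))
  # neutral relative risks: incidence identical across categories
  dbn <- toy_databook(effects = neutral_effect_sizes())
  pn <- calibrate(dbn, verbose = FALSE)
  incn <- diarrhea_incidence(pn, coverage_vector(), "12-23m")
  expect_equal(unname(diff(range(incn))), 0)
})

test_that("baseline projections are stationary and reproduce the inputs", {
  db <- demo_db()
  traj <- run_projection(db, demo_params())
  s <- traj$summary
  expect_equal(projected_u5mr(traj), 46, tolerance = 46 * 0.005)
  drift <- abs(s$stunting_prevalence[nrow(s)] - s$stunting_prevalence[1])
  expect_lt(drift, 0.01)
  expect_equal(unname(traj$band_stunting_prevalence),
               unname(nutriopt:::stunted_fraction(db$risks$stunting_distribution)),
               tolerance = 0.01)
  # cumulative series are non-decreasing
  expect_true(all(diff(s$cum_deaths) >= 0))
  expect_true(all(diff(s$cum_graduates_not_stunted) >= 0))
  # zero-length horizon: empty trajectory, zero cumulatives
  t0 <- run_projection(db, demo_params(), months = 0)
  expect_equal(nrow(t0$summary), 0)
  expect_equal(t0$cumulative$deaths_total, 0)
  expect_equal(t0$cumulative$graduates_total, 0)
  # determinism: identical inputs give bit-identical trajectories
  ta <- run_projection(db, demo_params(), months = 18)
  tb <- run_projection(db, demo_params(), months = 18)
  expect_identical(ta$summary, tb$summary)
})

test_that("defunding all programs never reduces deaths", {
  problem <- demo_problem()
  sq <- project_to_simplex(baseline_spending(demo_db()),
                           problem$total_budget)
  zero <- setNames(rep(0, 6), names(sq))
  o_zero <- nutriopt:::allocation_outcomes(problem, zero)
  o_base <- nutriopt:::allocation_outcomes(problem, sq)
  expect_gte(o_zero$deaths, o_base$deaths)
  expect_lte(o_zero$alive_not_stunted, o_base$alive_not_stunted)
})

test_that("trajectories export as tidy long CSV", {
  traj <- run_projection(demo_db(), demo_params(), months = 6)
  long <- trajectory_long(traj)
  expect_setequal(unique(long$metric),
                  setdiff(colnames(traj$summary), "month"))
  expect_equal(nrow(long), 6 * 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(long))
  expect_identical(colnames(back), c("month", "metric", "value"))
})
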