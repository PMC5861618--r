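test_that("databook round-trips through YAML byte-stably", {
  db <- demo_db()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_databook(db, f1)
  db2 <- read_databook(f1)
  write_databook(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(db2$risks$stunting_distribution, db$risks$stunting_distribution,
               tolerance = 1e-12)
  expect_equal(db2$demographics$population_per_band,
               db$demographics$population_per_band, tolerance = 1e-12)
  expect_identical(names(db2$interventions), names(db$interventions))
})

test_that("loading a databook with a missing block names the block", {
  db <- demo_db()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_databook(db, f)
  txt <- readLines(f)
  top <- grep("^[a-z_]+:", txt)
  mort <- grep("^mortality:", txt)
  nxt <- min(top[top > mort])
  writeLines(txt[-(mort:(nxt - 1))], f)
  expect_error(read_databook(f), "mortality")
  expect_error(read_databook(tempfile()), "not found")
})

test_that("validation reports distribution, coverage and block violations", {
  db <- demo_db()
  expect_length(validate_databook(db), 0)

  bad <- db
  bad$risks$breastfeeding_distribution["1-5m", "none"] <-
    bad$risks$breastfeeding_distribution["1-5m", "none"] - 0.1
  v <- validate_databook(bad)
  expect_length(v, 1)
  expect_match(v, "breastfeeding_distribution band 1-5m", fixed = TRUE)

  bad2 <- db
  bad2$interventions$VAS$baseline_coverage <- 0.99
  bad2$interventions$VAS$saturation <- 0.9
  expect_match(validate_databook(bad2), "VAS.*saturation", all = FALSE)

  bad3 <- unclass(db)
  bad3$mortality <- NULL
  expect_match(validate_databook(bad3), "missing block 'mortality'",
               all = FALSE)

  # a clean per-band distribution passes
  ok <- db
  ok$risks$stunting_distribution[] <- rep(c(0.4, 0.3, 0.2, 0.1), each = 5)
  expect_length(validate_databook(ok), 0)
})

test_that("the national fixture matches the published setting", {
  db <- demo_db()
  expect_equal(db$interventions$VAS$unit_cost, 0.35)
  expect_equal(db$interventions$IYCF$baseline_coverage, 0.247)
  expect_equal(db$interventions$BFP$baseline_coverage, 0.61)
  expect_equal(db$interventions$BEP$unit_cost, 25.00)
  expect_equal(db$interventions$AMS$unit_cost, 1.80)
  expect_equal(db$interventions$CFS$unit_cost, 48.00)
  expect_equal(db$mortality$u5mr, 46)
  expect_equal(db$mortality$neonatal_share, 0.5)
  expect_equal(aggregate_stunting_prevalence(db), 0.36, tolerance = 0.005)
  expect_equal(db$risks$breastfeeding_distribution["<1m", "exclusive"], 0.61)
  expect_equal(sum(db$demographics$population_per_band), 15e6,
               tolerance = 0.05)
  expect_true(isTRUE(db$effects$placeholder))
  # pure function of the seed
  expect_identical(generate_demo_databook(7), generate_demo_databook(7))
})

test_that("region fixtures carry the stated geographic heterogeneity", {
  rs <- demo_regions()
  expect_setequal(names(rs$regions),
                  c("Barisal", "Chittagong", "Dhaka", "Khulna", "Rajshahi",
                    "Rangpur", "Sylhet"))
  for (db in rs$regions) expect_length(validate_databook(db), 0)

  prev <- vapply(rs$regions, aggregate_stunting_prevalence, 0)
  expect_identical(names(which.max(prev)), "Sylhet")
  expect_gt(prev[["Sylhet"]], prev[["Khulna"]])

  pov <- vapply(rs$regions, function(d) d$demographics$poverty_fraction, 0)
  expect_identical(names(which.max(pov)), "Sylhet")

  cases <- vapply(rs$regions, function(d) {
    sum(d$demographics$population_per_band *
          nutriopt:::stunted_fraction(d$risks$stunting_distribution))
  }, 0)
  expect_identical(names(which.max(cases)), "Dhaka")

  pops <- vapply(rs$regions,
                 function(d) sum(d$demographics$population_per_band), 0)
  national <- sum(demo_db()$demographics$population_per_band)
  expect_equal(sum(pops), national, tolerance = 0.01)

  # region set round-trips through a directory of databooks
  dir <- withr::local_tempdir()
  write_region_set(rs, dir)
  rs2 <- read_region_set(dir)
  expect_setequal(names(rs2$regions), names(rs$regions))
  expect_equal(rs2$regions$Sylhet$demographics$poverty_fraction,
               rs$regions$Sylhet$demographics$poverty_fraction)
})
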