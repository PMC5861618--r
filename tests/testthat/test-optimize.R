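test_that("simplex projection rescales, clamps and is idempotent", {
  expect_equal(project_to_simplex(c(10, 10), 30), c(15, 15))
  expect_equal(project_to_simplex(c(10, 10), 30, upper = c(12, Inf)),
               c(12, 18))
  x <- project_to_simplex(c(3, 9, 0.5), 20, lower = c(1, 0, 0),
                          upper = c(8, 15, 20))
  expect_equal(sum(x), 20, tolerance = 1e-9)
  expect_true(all(x >= c(1, 0, 0) - 1e-12 & x <= c(8, 15, 20) + 1e-12))
  expect_equal(project_to_simplex(x, 20, lower = c(1, 0, 0),
                                  upper = c(8, 15, 20)), x,
               tolerance = 1e-12)
  # all at zero: the budget is spread over the free programs
  expect_equal(project_to_simplex(c(0, 0, 0), 9), c(3, 3, 3))
  expect_error(project_to_simplex(c(1, 1), 10, upper = c(2, 2)),
               "infeasible")
})

test_that("ASD recovers the quadratic Lagrange optimum on the simplex", {
  c0 <- c(10, 25, 5, 40)
  B <- 100
  f <- function(x) sum((x - c0)^2)
  xstar <- c0 + (B - sum(c0)) / length(c0)
  res <- asd_minimize(f, rep(B / 4, 4), B, control = list(seed = 3))
  expect_lt(max(abs(res$best_allocation - xstar)), 0.001 * B)
  # feasibility of the result
  expect_equal(sum(res$best_allocation), B, tolerance = 1e-9)
  expect_true(all(res$best_allocation >= -1e-12))
})

test_that("ASD sends all budget to a strictly dominant linear direction", {
  s <- c(5, 1, 0.5)
  f <- function(x) -sum(s * x)
  res <- asd_minimize(f, c(30, 30, 30), 90, control = list(seed = 2))
  expect_gt(res$best_allocation[1], 90 * 0.999)
})

test_that("ASD is bit-reproducible from its seed", {
  f <- function(x) sum((x - c(1, 2, 3))^2)
  r1 <- asd_minimize(f, c(2, 2, 2), 6, control = list(seed = 9))
  r2 <- asd_minimize(f, c(2, 2, 2), 6, control = list(seed = 9))
  expect_identical(r1$best_allocation, r2$best_allocation)
  expect_identical(r1$evaluations, r2$evaluations)
})

test_that("objective evaluation is deterministic and guards feasibility", {
  problem <- demo_problem()
  sq <- project_to_simplex(problem$status_quo, problem$total_budget)
  expect_identical(evaluate_objective(problem, sq),
                   evaluate_objective(problem, sq))
  expect_error(evaluate_objective(problem, sq * 2), "infeasible")
  # zero-length horizon gives a zero alive-and-not-stunted count
  p0 <- optimization_problem(demo_db(), demo_params(), months = 0)
  expect_equal(evaluate_objective(p0, sq), 0)
})

test_that("full-model ASD matches a fine grid search on two programs", {
  db <- demo_db()
  db$interventions <- db$interventions[c("IYCF", "VAS")]
  params <- demo_params()
  problem <- optimization_problem(db, params, total_budget = 8e6,
                                  months = 60)
  f <- function(x) evaluate_objective(problem, x)
  splits <- seq(0, 8e6, length.out = 101)
  fg <- vapply(splits, function(s) f(c(IYCF = s, VAS = 8e6 - s)), 0)
  best_grid <- min(fg)
  worst_grid <- max(fg)
  res <- optimize_allocation(problem, light_ctrl(seed = 4))
  # the stochastic optimum agrees with the grid to well under 1% of the
  # objective range
  expect_lt(res$objective_value - best_grid,
            0.01 * (worst_grid - best_grid))
  # and fixed seeds give bit-identical repeat runs
  res2 <- optimize_allocation(problem, light_ctrl(seed = 4))
  expect_identical(res$best_allocation, res2$best_allocation)
})

test_that("a program with nothing to offer is defunded", {
  db <- demo_db()
  db$interventions <- db$interventions[c("IYCF", "BEP")]
  db$effects$program_effects$bep_birth_or <- 1  # zero efficacy
  params <- calibrate(db, verbose = FALSE)
  problem <- optimization_problem(db, params, total_budget = 6e6,
                                  months = 60)
  res <- optimize_allocation(problem, light_ctrl(seed = 5))
  expect_gt(res$best_allocation[["IYCF"]], 0.99 * 6e6)
  # the optimizer never reports worse than the status quo
  expect_lte(res$objective_value, res$objective_status_quo + 1e-9)
})

test_that("budget scans are monotone and anchored at multiplier one", {
  problem <- demo_problem()
  ctrl <- light_ctrl(seed = 6, max_evals = 250, stall_window = 80,
                     restarts = 1)
  expect_identical(budget_scan(problem, numeric(0), ctrl)$results,
                   list())
  scan <- budget_scan(problem, c(1, 2), ctrl)
  solo <- optimize_allocation(problem, ctrl)
  expect_identical(scan$results[["1"]]$best_allocation,
                   solo$best_allocation)
  # natural-sense objective cannot worsen as the budget grows
  expect_true(all(diff(scan$table$objective) >= -1e-9))
})
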