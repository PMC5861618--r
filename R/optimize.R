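# Budget optimization: objective functions over the epidemiological
# projection, simplex-constrained allocation handling, and an adaptive
# stochastic descent (ASD) optimizer that learns per-direction step sizes
# and selection probabilities from accepted and rejected moves.

#' Define a budget-optimization problem
#'
#' Bundles a calibrated model, the programs' cost functions, an objective
#' and a total annual budget into a problem that [evaluate_objective()] and
#' [optimize_allocation()] consume. Objectives: `alive_not_stunted`
#' (cumulative children reaching age five alive and not stunted over the
#' horizon; maximized, the default), `deaths` (cumulative under-5 deaths;
#' minimized), `stunting_prevalence_end` (all-under-5 stunting prevalence in
#' the final month; minimized).
#'
#' @param db a validated databook.
#' @param params calibrated parameters; calibrated from `db` when `NULL`.
#' @param objective objective name.
#' @param total_budget annual budget in USD; defaults to the databook's
#'   estimated current spending, `sum(baseline_spending(db))`.
#' @param bounds optional list with `lower` and/or `upper` named vectors of
#'   per-program spending bounds (USD/year).
#' @param months projection length in months; defaults to the databook
#'   horizon.
#' @return an object of class `optimization_problem`.
#' @export
optimization_problem <- function(db, params = NULL,
                                 objective = c("alive_not_stunted", "deaths",
                                               "stunting_prevalence_end"),
                                 total_budget = NULL, bounds = NULL,
                                 months = NULL) {
  objective <- match.arg(objective)
  if (is.null(params)) params <- calibrate(db, verbose = FALSE)
  status_quo <- baseline_spending(db)
  if (is.null(total_budget)) total_budget <- sum(status_quo)
  if (is.null(months)) {
    months <- 12L * (db$horizon$end_year - db$horizon$start_year + 1L)
  }
  programs <- names(db$interventions)
  lower <- setNames(rep(0, length(programs)), programs)
  upper <- setNames(rep(Inf, length(programs)), programs)
  if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
  if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  if (sum(lower) > total_budget + 1e-9) {
    stop("infeasible bounds: minimum spending exceeds the total budget",
         call. = FALSE)
  }
  structure(
    list(db = db, params = params,
         cost_functions = databook_cost_functions(db),
         objective = objective,
         sense = if (objective == "alive_not_stunted") "maximize"
                 else "minimize",
         total_budget = total_budget,
         lower = lower, upper = upper,
         months = months, programs = programs,
         status_quo = status_quo,
         init_counts = initialize_state(db)$counts,
         births = monthly_births_series(db, months)),
    class = "optimization_problem")
}

#' @export
print.optimization_problem <- function(x, ...) {
  cat("<optimization_problem>", x$db$region_name, "\n")
  cat(sprintf("  objective: %s (%s); budget $%.2f m/year; horizon %d months\n",
              x$objective, x$sense, x$total_budget / 1e6, x$months))
  invisible(x)
}

# allocation -> coverage vector through the cost functions (programs absent
# from the databook stay at zero coverage)
allocation_to_coverage <- function(problem, alloc) {
  cov <- setNames(numeric(length(intervention_names())),
                  intervention_names())
  for (nm in problem$programs) {
    cov[[nm]] <- coverage_from_spending(problem$cost_functions[[nm]],
                                        alloc[[nm]])
  }
  cov
}

# raw (natural-sense) outcome metrics of an allocation; a flattened
# (80-vector) replica of the step_core update that skips the per-cause
# bookkeeping the objectives do not need
allocation_outcomes <- function(problem, alloc) {
  coverage <- allocation_to_coverage(problem, alloc)
  engine <- build_engine(problem$params, coverage)
  surv <- 1 - unlist(engine$r_tot, use.names = FALSE)
  winv <- rep(1 / engine$widths, each = 16L)
  Tbig <- matrix(0, 80, 80)
  for (a in 1:4) {
    Tbig[(16 * a + 1):(16 * a + 16), (16 * a - 15):(16 * a)] <-
      engine$trans[[a]]
  }
  entry <- engine$entry
  grad_idx <- 64L + which(!stunted_mask())
  births <- problem$births
  months <- problem$months
  x <- as.vector(problem$init_counts)
  mid <- x
  cum_deaths <- 0
  cum_grad_ns <- 0
  for (t in seq_len(months)) {
    x[1:16] <- x[1:16] + births[t] * entry
    pre <- sum(x)
    x <- x * surv
    cum_deaths <- cum_deaths + (pre - sum(x))
    if (t == months) mid <- x
    out <- x * winv
    x <- x - out + as.vector(Tbig %*% out)
    cum_grad_ns <- cum_grad_ns + sum(out[grad_idx])
  }
  prev <- sum(mid[rep(stunted_mask(), 5)]) / sum(mid)
  list(alive_not_stunted = cum_grad_ns, deaths = cum_deaths,
       stunting_prevalence_end = prev)
}

#' Evaluate the objective of an allocation
#'
#' Maps the allocation to coverages through the cost functions, projects the
#' model over the horizon, and returns the objective value in canonical
#' minimization sense (maximization objectives are negated). Deterministic.
#'
#' @param problem an `optimization_problem`.
#' @param alloc named spending per program, summing to the problem budget.
#' @return a scalar (smaller is better).
#' @export
evaluate_objective <- function(problem, alloc) {
  if (any(alloc < -1e-9) ||
      abs(sum(alloc) - problem$total_budget) >
        1e-6 * max(problem$total_budget, 1)) {
    stop("infeasible allocation: must be non-negative and sum to the budget",
         call. = FALSE)
  }
  val <- allocation_outcomes(problem, alloc)[[problem$objective]]
  if (problem$sense == "maximize") -val else val
}

#' Project an allocation onto the budget simplex
#'
#' Returns the nearest-in-shape feasible allocation: non-negative, within
#' the bounds, summing to the total budget. Implemented as proportional
#' rescaling of the free portion with iterative clamping of entries that hit
#' a bound. Idempotent on feasible points.
#'
#' @param alloc a spending vector (any non-negative scale).
#' @param total_budget required sum.
#' @param lower,upper per-program bounds (recycled scalars allowed).
#' @return a feasible allocation.
#' @export
project_to_simplex <- function(alloc, total_budget, lower = 0, upper = Inf) {
  n <- length(alloc)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (sum(lower) > total_budget + 1e-9 ||
      sum(pmin(upper, total_budget)) < total_budget - 1e-9) {
    stop("infeasible bounds for the requested budget", call. = FALSE)
  }
  x <- pmin(pmax(alloc, lower), upper)
  fixed <- rep(FALSE, n)
  for (iter in seq_len(2 * n + 2)) {
    rem <- total_budget - sum(x[fixed])
    free <- which(!fixed)
    if (length(free) == 0) break
    base <- x[free] - lower[free]
    target <- rem - sum(lower[free])
    if (sum(base) <= 1e-12 * max(total_budget, 1)) {
      x[free] <- lower[free] + target / length(free)
    } else {
      x[free] <- lower[free] + base * (target / sum(base))
    }
    over <- free[x[free] > upper[free] + 1e-12]
    under <- free[x[free] < lower[free] - 1e-12]
    if (length(over) == 0 && length(under) == 0) break
    x[over] <- upper[over]
    x[under] <- lower[under]
    fixed[c(over, under)] <- TRUE
  }
  names(x) <- names(alloc)
  x
}

default_asd_control <- function(total_budget) {
  list(step_init = 0.1, step_grow = 2.0, step_shrink = 0.5,
       prob_grow = 2.0, prob_shrink = 0.5,
       max_evals = 2000L, stall_window = 100L, seed = 1L,
       step_floor = 1e-8 * total_budget)
}

#' Adaptive stochastic descent on the budget simplex
#'
#' Iteratively proposes single-coordinate steps (projected back onto the
#' budget simplex), sampling the coordinate and direction with probability
#' proportional to a learned weight. An accepted move (objective improves)
#' multiplies that direction's step size and weight by growth factors; a
#' rejected move shrinks them. Stops after `max_evals` objective evaluations
#' or `stall_window` consecutive evaluations without improvement. Fully
#' reproducible from the control seed.
#'
#' @param f objective evaluator: a deterministic function of an allocation,
#'   smaller is better.
#' @param x0 starting allocation (projected to feasibility first).
#' @param total_budget budget the allocation must sum to.
#' @param lower,upper per-program bounds.
#' @param control list of ASD hyperparameters; see
#'   `nutriopt:::default_asd_control` (initial step 10% of budget, growth
#'   2.0, decay 0.5, probability growth/decay 2.0/0.5, stall window 100,
#'   max 2000 evaluations).
#' @return an object of class `optimization_result` with the best
#'   allocation, objective values, evaluation count and convergence reason.
#' @export
asd_minimize <- function(f, x0, total_budget, lower = 0, upper = Inf,
                         control = list()) {
  ctrl <- modifyList(default_asd_control(total_budget), control)
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  set.seed(ctrl$seed)
  x <- project_to_simplex(x0, total_budget, lower, upper)
  fx <- f(x)
  evals <- 1L
  stall <- 0L
  ndir <- 2L * n
  steps <- rep(ctrl$step_init * total_budget, ndir)
  probs <- rep(1, ndir)
  f0 <- fx
  while (evals < ctrl$max_evals && stall < ctrl$stall_window) {
    k <- sample.int(ndir, 1L, prob = probs / sum(probs))
    i <- (k - 1L) %/% 2L + 1L
    sgn <- if (k %% 2L == 1L) 1 else -1
    xp <- x
    xp[i] <- xp[i] + sgn * steps[k]
    xp <- project_to_simplex(xp, total_budget, lower, upper)
    fp <- f(xp)
    evals <- evals + 1L
    if (fp < fx) {
      x <- xp
      fx <- fp
      steps[k] <- min(steps[k] * ctrl$step_grow, total_budget)
      probs[k] <- probs[k] * ctrl$prob_grow
      stall <- 0L
    } else {
      steps[k] <- max(steps[k] * ctrl$step_shrink, ctrl$step_floor)
      probs[k] <- max(probs[k] * ctrl$prob_shrink, 1e-9)
      stall <- stall + 1L
    }
    if (max(probs) > 1e12) probs <- probs / max(probs)
  }
  structure(
    list(best_allocation = x, objective_value = fx,
         objective_initial = f0, evaluations = evals,
         convergence = if (stall >= ctrl$stall_window) "stalled"
                       else "max_evals",
         seed = ctrl$seed),
    class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result>", x$convergence, "after", x$evaluations,
      "evaluations\n")
  cat("  objective (canonical min sense):",
      format(x$objective_value, digits = 8), "\n")
  if (!is.null(x$objective_status_quo)) {
    cat("  status quo:", format(x$objective_status_quo, digits = 8), "\n")
  }
  alloc <- x$best_allocation
  sh <- 100 * alloc / sum(alloc)
  for (nm in names(alloc)) {
    cat(sprintf("  %-5s $%12s  (%5.1f%%)\n", nm,
                format(round(alloc[[nm]]), big.mark = ","), sh[[nm]]))
  }
  invisible(x)
}

#' Optimize the allocation of a budget across programs
#'
#' Runs [asd_minimize()] from multiple starting points — the status-quo
#' allocation (rescaled to the budget) plus random points on the budget
#' simplex — and returns the best result, with the status-quo objective
#' recorded for comparison.
#'
#' @param problem an `optimization_problem`.
#' @param control ASD control list; `restarts` (default 3) and `seed` are
#'   also read from it. Extra starting allocations can be supplied as a
#'   list in `control$extra_starts`.
#' @return an `optimization_result`.
#' @export
optimize_allocation <- function(problem, control = list()) {
  ctrl <- modifyList(default_asd_control(problem$total_budget), control)
  restarts <- if (is.null(control$restarts)) 3L else control$restarts
  f <- function(x) evaluate_objective(problem, x)
  sq <- project_to_simplex(problem$status_quo, problem$total_budget,
                           problem$lower, problem$upper)
  f_sq <- f(sq)
  starts <- list(sq)
  if (!is.null(control$extra_starts)) {
    starts <- c(starts, control$extra_starts)
  }
  if (restarts > length(starts)) {
    set.seed(ctrl$seed + 1000L)
    for (k in seq_len(restarts - length(starts))) {
      g <- rexp(length(problem$programs))
      starts <- c(starts, list(setNames(
        problem$total_budget * g / sum(g), problem$programs)))
    }
  }
  best <- NULL
  total_evals <- 0L
  for (k in seq_along(starts)) {
    res <- asd_minimize(f, starts[[k]], problem$total_budget,
                        problem$lower, problem$upper,
                        modifyList(ctrl, list(seed = ctrl$seed + k - 1L)))
    total_evals <- total_evals + res$evaluations
    if (is.null(best) || res$objective_value < best$objective_value) {
      best <- res
    }
  }
  best$evaluations <- total_evals
  best$objective_status_quo <- f_sq
  best$status_quo_allocation <- sq
  best$objective_name <- problem$objective
  best$sense <- problem$sense
  best$seed <- ctrl$seed
  # the status quo is itself a visited start, so the optimum is never worse
  if (best$objective_value > f_sq) {
    best$best_allocation <- sq
    best$objective_value <- f_sq
  }
  best
}

#' Optimize over a ladder of total budgets
#'
#' Re-optimizes the allocation at each multiple of the problem's reference
#' budget. Each run is seeded with the previous optimum (rescaled to the new
#' total) in addition to the usual starting points, which makes the optimal
#' objective sequence monotone non-worsening in budget.
#'
#' @param problem an `optimization_problem`; its `total_budget` is the
#'   reference (100%) budget.
#' @param multipliers positive budget multipliers, e.g.
#'   `c(0.25, 0.5, 1, 1.5, 2, 3, 4)`.
#' @param control ASD control list.
#' @return a list with `table` (a data frame of budget, objective at the
#'   optimum in natural sense, and per-program spending) and `results` (the
#'   `optimization_result` per multiplier).
#' @export
budget_scan <- function(problem, multipliers, control = list()) {
  stopifnot(all(multipliers > 0))
  results <- list()
  rows <- list()
  prev <- NULL
  for (j in seq_along(multipliers)) {
    mult <- multipliers[j]
    pj <- problem
    pj$total_budget <- problem$total_budget * mult
    ctrl <- control
    if (!is.null(prev)) {
      ctrl$extra_starts <- list(prev * pj$total_budget / sum(prev))
    }
    res <- optimize_allocation(pj, ctrl)
    prev <- res$best_allocation
    natural <- if (problem$sense == "maximize") -res$objective_value else
      res$objective_value
    results[[as.character(mult)]] <- res
    rows[[j]] <- data.frame(multiplier = mult, budget = pj$total_budget,
                            objective = natural,
                            t(res$best_allocation))
  }
  list(table = do.call(rbind, rows), results = results)
}
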