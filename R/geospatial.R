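# Geospatial layer: per-region budget-outcome curves (best attainable
# objective as a function of the regional budget, interpolated monotonically
# between optimized grid points) and optimization of the split of a national
# budget across regions, followed by within-region refinement.

#' Construct a budget-outcome curve
#'
#' Usually built by [build_budget_outcome_curve()]; the constructor is
#' exported so that curves can also be assembled from precomputed grids.
#' The interpolant is a monotone shape-preserving piecewise cubic (Hyman
#' filtering) through the grid points, clamped to the end values outside
#' the grid.
#'
#' @param region_name region label.
#' @param budgets strictly increasing grid of annual budgets (USD).
#' @param objectives best attainable objective at each budget, in natural
#'   sense (see `sense`).
#' @param sense `"maximize"` or `"minimize"`; used to enforce monotone
#'   non-worsening values along the grid.
#' @return an object of class `budget_outcome_curve`; call it via
#'   [predict_curve()].
#' @export
budget_outcome_curve <- function(region_name, budgets, objectives,
                                 sense = "maximize") {
  stopifnot(length(budgets) == length(objectives), length(budgets) >= 3,
            all(diff(budgets) > 0))
  # more budget can never worsen the best attainable outcome; enforce it on
  # the grid before interpolating so optimizer noise cannot oscillate
  vals <- if (sense == "maximize") cummax(objectives) else cummin(objectives)
  fun <- stats::splinefun(budgets, vals, method = "hyman")
  structure(list(region_name = region_name, budgets = budgets,
                 objectives = vals, sense = sense, interpolant = fun),
            class = "budget_outcome_curve")
}

#' Evaluate a budget-outcome curve
#'
#' @param curve a `budget_outcome_curve`.
#' @param budget annual budget(s) in USD; values outside the grid are
#'   clamped to the end points.
#' @return interpolated best attainable objective value(s).
#' @export
predict_curve <- function(curve, budget) {
  b <- pmin(pmax(budget, curve$budgets[1]),
            curve$budgets[length(curve$budgets)])
  curve$interpolant(b)
}

#' @export
print.budget_outcome_curve <- function(x, ...) {
  cat("<budget_outcome_curve>", x$region_name, "-", x$sense, "\n")
  print(data.frame(budget = x$budgets, objective = x$objectives),
        row.names = FALSE)
  invisible(x)
}

#' Build a region's budget-outcome curve
#'
#' Optimizes the within-region allocation at each grid budget (multiples of
#' the region's estimated current spending) and interpolates the optimized
#' objective values with a monotone shape-preserving cubic.
#'
#' @param region_db the region's databook.
#' @param grid_multipliers at least three positive multipliers of current
#'   regional spending; default `c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4)`.
#' @param objective objective name (see [optimization_problem()]).
#' @param control ASD control list, passed to [budget_scan()].
#' @param params optional pre-calibrated parameters for the region.
#' @return a `budget_outcome_curve`.
#' @export
build_budget_outcome_curve <- function(region_db,
                                       grid_multipliers =
                                         c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4),
                                       objective = "alive_not_stunted",
                                       control = list(), params = NULL) {
  stopifnot(length(grid_multipliers) >= 3)
  problem <- optimization_problem(region_db, params = params,
                                  objective = objective)
  scan <- budget_scan(problem, sort(grid_multipliers), control)
  budget_outcome_curve(region_db$region_name, scan$table$budget,
                       scan$table$objective, problem$sense)
}

#' Optimize the split of a national budget across regions
#'
#' Adaptive stochastic descent over the region-budget simplex, scoring a
#' split by the sum of the regions' interpolated budget-outcome curves.
#'
#' @param curves list of `budget_outcome_curve`s (same objective sense).
#' @param national_budget total annual budget to split (USD).
#' @param control ASD control list; `lower` per-region bounds can be set via
#'   `control$lower` (e.g. to forbid de-funding any region).
#' @return named budget per region, summing to `national_budget`.
#' @export
optimize_across_regions <- function(curves, national_budget,
                                    control = list()) {
  nms <- vapply(curves, `[[`, "", "region_name")
  names(curves) <- nms
  sense <- curves[[1]]$sense
  if (length(curves) == 1) {
    return(setNames(national_budget, nms))
  }
  f <- function(split) {
    tot <- sum(vapply(seq_along(curves), function(i) {
      predict_curve(curves[[i]], split[i])
    }, 0))
    if (sense == "maximize") -tot else tot
  }
  lower <- if (is.null(control$lower)) 0 else control$lower
  # start from each region's mid-grid budget, projected to the national total
  x0 <- vapply(curves, function(cu) {
    cu$budgets[ceiling(length(cu$budgets) / 2)]
  }, 0)
  ctrl <- modifyList(
    list(max_evals = 5000L, stall_window = 400L, seed = 1L), control)
  restarts <- if (is.null(control$restarts)) 3L else control$restarts
  best <- NULL
  starts <- list(x0)
  if (!is.null(control$extra_starts)) {
    starts <- c(starts, control$extra_starts)
  }
  set.seed(ctrl$seed + 2000L)
  for (k in seq_len(max(restarts - 1L, 0L))) {
    g <- rexp(length(curves))
    starts <- c(starts, list(national_budget * g / sum(g)))
  }
  for (k in seq_along(starts)) {
    res <- asd_minimize(f, starts[[k]], national_budget, lower = lower,
                        control = modifyList(ctrl,
                                             list(seed = ctrl$seed + k - 1L)))
    if (is.null(best) || res$objective_value < best$objective_value) {
      best <- res
    }
  }
  setNames(best$best_allocation, nms)
}

#' Re-optimize within regions at an allocated split
#'
#' Runs [optimize_allocation()] per region at its allocated budget; the
#' national objective is the sum of the regional objectives (regions are
#' independent).
#'
#' @param split named budget per region (USD/year).
#' @param region_dbs named list of region databooks (a `region_set`'s
#'   `regions` element).
#' @param objective objective name.
#' @param control ASD control list.
#' @param params_list optional named list of pre-calibrated parameters.
#' @return an object of class `regional_allocation`: per-region budgets,
#'   per-region program allocations, per-region and national objective
#'   values (natural sense).
#' @export
refine_within_regions <- function(split, region_dbs,
                                  objective = "alive_not_stunted",
                                  control = list(), params_list = NULL,
                                  extra_starts = NULL) {
  stopifnot(all(names(split) %in% names(region_dbs)))
  out <- list()
  objs <- setNames(numeric(length(split)), names(split))
  for (nm in names(split)) {
    problem <- optimization_problem(
      region_dbs[[nm]], params = params_list[[nm]], objective = objective,
      total_budget = split[[nm]])
    ctrl_nm <- control
    if (!is.null(extra_starts[[nm]])) {
      ctrl_nm$extra_starts <- c(ctrl_nm$extra_starts,
                                list(extra_starts[[nm]]))
    }
    res <- optimize_allocation(problem, ctrl_nm)
    out[[nm]] <- res
    objs[nm] <- if (problem$sense == "maximize") -res$objective_value else
      res$objective_value
  }
  structure(list(split = split, results = out,
                 regional_objectives = objs,
                 national_objective = sum(objs),
                 objective = objective),
            class = "regional_allocation")
}

#' Full geospatial optimization of a national budget
#'
#' Builds a budget-outcome curve per region, optimizes the split of the
#' national budget across regions, and refines within-region allocations at
#' the chosen split. The current (status-quo) split is always evaluated as a
#' candidate too, along with any caller-supplied reference splits, and the
#' best refined result is returned — so the geographic optimum is never
#' worse than the references it was given.
#'
#' @param region_dbs named list of region databooks.
#' @param national_budget total annual budget; defaults to the summed
#'   current regional spending.
#' @param objective objective name.
#' @param grid_multipliers grid for the budget-outcome curves.
#' @param control ASD control list.
#' @param params_list optional named list of pre-calibrated parameters.
#' @param reference_splits optional list of additional named splits to
#'   evaluate as candidates (each is projected to the national budget).
#' @param reference_allocations optional named list (per region) of
#'   program allocations used as additional optimizer starts during
#'   refinement (projected to each candidate's regional budget).
#' @return a list with `best` (a `regional_allocation`), `curves`, the
#'   optimized `split`, and `candidates` (all refined candidates).
#' @export
geospatial_optimize <- function(region_dbs, national_budget = NULL,
                                objective = "alive_not_stunted",
                                grid_multipliers =
                                  c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4),
                                control = list(), params_list = NULL,
                                reference_splits = NULL,
                                reference_allocations = NULL) {
  if (is.null(params_list)) {
    params_list <- lapply(region_dbs, calibrate, verbose = FALSE)
  }
  current <- vapply(region_dbs, function(db) sum(baseline_spending(db)), 0)
  if (is.null(national_budget)) national_budget <- sum(current)
  curves <- lapply(names(region_dbs), function(nm) {
    build_budget_outcome_curve(region_dbs[[nm]], grid_multipliers,
                               objective = objective, control = control,
                               params = params_list[[nm]])
  })
  split_ctrl <- control
  split_ctrl$extra_starts <- c(
    list(unname(current)),
    lapply(reference_splits, function(s) unname(s[names(region_dbs)])))
  split <- optimize_across_regions(curves, national_budget, split_ctrl)

  candidates <- c(list(optimized = split,
                       current = setNames(
                         project_to_simplex(current, national_budget),
                         names(current))),
                  lapply(reference_splits, function(s) {
                    setNames(project_to_simplex(s[names(region_dbs)],
                                                national_budget),
                             names(region_dbs))
                  }))
  refined <- lapply(candidates, function(sp) {
    refine_within_regions(sp, region_dbs, objective = objective,
                          control = control, params_list = params_list,
                          extra_starts = reference_allocations)
  })
  objs <- vapply(refined, `[[`, 0, "national_objective")
  sense_max <- objective == "alive_not_stunted"
  best <- refined[[if (sense_max) which.max(objs) else which.min(objs)]]
  list(best = best, curves = curves, split = split, candidates = refined)
}

#' @export
print.regional_allocation <- function(x, ...) {
  cat("<regional_allocation>", x$objective, "- national objective",
      format(x$national_objective, digits = 8), "\n")
  for (nm in names(x$split)) {
    cat(sprintf("  %-11s $%12s -> %s\n", nm,
                format(round(x$split[[nm]]), big.mark = ","),
                format(x$regional_objectives[[nm]], digits = 6)))
  }
  invisible(x)
}
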