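# Scenario runner: load databooks, calibrate, run a scenario (baseline
# projection, single-budget optimization, budget scan, or geospatial
# optimization) and write tables, a JSON summary and a log. This is the
# surface the command-line wrapper drives.

#' Configure a scenario run
#'
#' @param mode one of `baseline`, `optimize`, `budget_scan`, `geospatial`.
#' @param objective objective name (see [optimization_problem()]).
#' @param budget_multiplier scalar (optimize) or vector (budget_scan) of
#'   multipliers of estimated current spending.
#' @param seed integer seed for the optimizer.
#' @param out_dir output directory (created if needed).
#' @param control optional ASD control overrides.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(mode = c("baseline", "optimize", "budget_scan",
                                     "geospatial"),
                            objective = "alive_not_stunted",
                            budget_multiplier = 1, seed = 1L,
                            out_dir = tempfile("scenario"),
                            control = list()) {
  mode <- match.arg(mode)
  if (mode == "budget_scan" && length(budget_multiplier) < 1) {
    stop("budget_scan mode requires at least one budget multiplier",
         call. = FALSE)
  }
  structure(list(mode = mode, objective = objective,
                 budget_multiplier = budget_multiplier, seed = seed,
                 out_dir = out_dir, control = control),
            class = "scenario_config")
}

#' Run a scenario and write result files
#'
#' Writes, into the configured output directory: `allocation.csv` (program,
#' status-quo spending, optimized spending and shares), `trajectory.csv`
#' (tidy month/metric/value series for the relevant projection),
#' `summary.json` (objective values, improvement versus status quo, seed,
#' placeholder-effects flag) and `log.txt` (calibration diagnostics).
#'
#' @param config a [scenario_config()].
#' @param databook_path path to a YAML databook, or (for `geospatial` mode)
#'   a region-set directory written by [write_region_set()].
#' @return the summary list, invisibly; files are written as a side effect.
#' @export
run_scenario <- function(config, databook_path) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mode: %s  objective: %s  seed: %d",
                         config$mode, config$objective, config$seed))
  ctrl <- modifyList(list(seed = config$seed), config$control)

  if (config$mode == "geospatial") {
    return(run_geospatial_scenario(config, databook_path, ctrl, log_lines))
  }

  db <- if (inherits(databook_path, "databook")) databook_path else
    read_databook(databook_path)
  params <- calibrate(db, verbose = FALSE)
  d <- params$diagnostics
  log_lines <- c(log_lines,
                 sprintf("calibration: U5MR %.3f/1000 (target %.3f), neonatal share %.4f (target %.4f)",
                         d$u5mr_simulated, d$u5mr_target,
                         d$neonatal_share_simulated,
                         d$neonatal_share_target),
                 sprintf("max band-entry stunting error: %.3g",
                         d$max_entry_stunting_error))
  if (d$placeholder_effects) {
    log_lines <- c(log_lines, "NOTE: placeholder effect sizes in use")
  }

  sq <- baseline_spending(db)
  summary <- list(mode = config$mode, region = db$region_name,
                  objective = config$objective, seed = config$seed,
                  placeholder_effects = d$placeholder_effects,
                  status_quo_spending = as.list(sq))

  if (config$mode == "baseline") {
    traj <- run_projection(db, params)
    write_trajectory_csv(traj, file.path(config$out_dir, "trajectory.csv"))
    alloc_tab <- data.frame(
      program = names(sq), spending = unname(sq),
      share_pct = unname(allocation_shares(sq, percent_digits = 0)))
    summary$objective_values <- allocation_outcomes(
      optimization_problem(db, params, objective = config$objective), sq)
    summary$final_stunting_prevalence <-
      traj$summary$stunting_prevalence[nrow(traj$summary)]
  } else if (config$mode == "optimize") {
    problem <- optimization_problem(
      db, params, objective = config$objective,
      total_budget = sum(sq) * config$budget_multiplier[1])
    res <- optimize_allocation(problem, ctrl)
    traj <- run_projection(db, params,
                           allocation_to_coverage(problem,
                                                  res$best_allocation))
    write_trajectory_csv(traj, file.path(config$out_dir, "trajectory.csv"))
    alloc_tab <- data.frame(
      program = names(sq), status_quo = unname(sq),
      optimized = unname(res$best_allocation[names(sq)]),
      status_quo_share_pct = unname(allocation_shares(sq, 0)),
      optimized_share_pct =
        unname(allocation_shares(res$best_allocation[names(sq)], 0)))
    imp <- report_improvement(res)
    summary$optimized_spending <- as.list(res$best_allocation)
    summary$objective_optimum <- res$objective_value
    summary$objective_status_quo <- res$objective_status_quo
    summary$improvement <- as.list(imp)
    log_lines <- c(log_lines,
                   sprintf("optimizer: %s after %d evaluations",
                           res$convergence, res$evaluations))
  } else { # budget_scan
    problem <- optimization_problem(db, params,
                                    objective = config$objective,
                                    total_budget = sum(sq))
    scan <- budget_scan(problem, config$budget_multiplier, ctrl)
    alloc_tab <- scan$table
    write.csv(scan$table, file.path(config$out_dir, "scan.csv"),
              row.names = FALSE, fileEncoding = "UTF-8")
    best <- scan$results[[length(scan$results)]]
    traj <- run_projection(db, params,
                           allocation_to_coverage(problem,
                                                  best$best_allocation))
    write_trajectory_csv(traj, file.path(config$out_dir, "trajectory.csv"))
    summary$scan <- lapply(seq_len(nrow(scan$table)), function(i) {
      as.list(scan$table[i, ])
    })
  }

  write.csv(alloc_tab, file.path(config$out_dir, "allocation.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(summary)
}

run_geospatial_scenario <- function(config, path, ctrl, log_lines) {
  rs <- if (inherits(path, "region_set")) path else read_region_set(path)
  national <- sum(vapply(rs$regions,
                         function(db) sum(baseline_spending(db)), 0)) *
    config$budget_multiplier[1]
  geo <- geospatial_optimize(rs$regions, national_budget = national,
                             objective = config$objective, control = ctrl)
  refined <- geo$best
  split <- refined$split
  log_lines <- c(log_lines,
                 sprintf("curves built for %d regions", length(rs$regions)))
  alloc_tab <- data.frame(
    region = names(split),
    status_quo = vapply(rs$regions[names(split)],
                        function(db) sum(baseline_spending(db)), 0),
    optimized = unname(split))
  write.csv(alloc_tab, file.path(config$out_dir, "allocation.csv"),
            row.names = FALSE, fileEncoding = "UTF-8")
  summary <- list(mode = "geospatial", objective = config$objective,
                  seed = config$seed,
                  national_budget = national,
                  split = as.list(split),
                  national_objective = refined$national_objective,
                  regional_objectives = as.list(refined$regional_objectives))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(summary)
}

#' Summarize the gain of an optimized allocation over the status quo
#'
#' @param result an `optimization_result` carrying a status-quo comparison
#'   (as produced by [optimize_allocation()]).
#' @return a one-row data frame with the objective value at the optimum and
#'   status quo (natural sense), the absolute improvement and the percent
#'   improvement (formatted to one decimal place in `improvement_pct_label`).
#' @export
report_improvement <- function(result) {
  if (is.null(result$objective_status_quo)) {
    stop("result carries no status-quo comparison", call. = FALSE)
  }
  sgn <- if (identical(result$sense, "maximize")) -1 else 1
  opt <- sgn * result$objective_value
  sq <- sgn * result$objective_status_quo
  # improvement is a gain for maximization, a reduction for minimization
  abs_impr <- if (identical(result$sense, "maximize")) opt - sq else sq - opt
  pct <- if (sq != 0) 100 * abs_impr / abs(sq) else 0
  data.frame(objective = result$objective_name %||% "objective",
             optimum = opt, status_quo = sq,
             improvement = abs_impr, improvement_pct = pct,
             improvement_pct_label = sprintf("%.1f%%", pct))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
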