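# Cost functions link annual spending on a program to coverage of its
# target group. The unit-cost parameterization uses a saturating
# tanh (shifted-logistic) curve through the origin whose slope at zero
# spending is exactly 1/(target population x unit cost) -- so the marginal
# cost at low coverage equals the unit cost -- and which approaches the
# saturation coverage as spending grows. Historical expenditure data can
# instead be fitted with a 3-parameter logistic.

#' Build a cost function
#'
#' `cost_function()` builds the 2-parameter unit-cost form,
#' `coverage = saturation * tanh(S / (saturation * P * u))`, which is linear
#' with marginal cost `u` at low spending and saturates at `saturation`.
#' `fit_cost_function()` (see below) fits the 3-parameter logistic form to
#' expenditure/coverage observations.
#'
#' @param unit_cost USD per beneficiary per year (marginal cost at low
#'   coverage).
#' @param target_pop_size number of people in the target group.
#' @param saturation maximum attainable coverage, in `(0, 1]`.
#' @return an object of class `cost_function`.
#' @export
cost_function <- function(unit_cost, target_pop_size, saturation = 0.95) {
  stopifnot(unit_cost > 0, target_pop_size > 0,
            saturation > 0, saturation <= 1)
  structure(list(form = "unit_cost_logistic", unit_cost = unit_cost,
                 target_pop_size = target_pop_size, saturation = saturation),
            class = "cost_function")
}

#' @export
print.cost_function <- function(x, ...) {
  if (x$form == "unit_cost_logistic") {
    cat(sprintf(
      "<cost_function> unit-cost form: $%.2f/beneficiary, target %s, saturation %.0f%%\n",
      x$unit_cost, format(round(x$target_pop_size), big.mark = ","),
      100 * x$saturation))
  } else {
    cat(sprintf("<cost_function> fitted logistic: L=%.4f k=%.4g S0=%.4g\n",
                x$L, x$k, x$S0))
  }
  invisible(x)
}

#' Coverage attained by a level of annual spending
#'
#' @param cf a `cost_function`.
#' @param spending annual spending in USD (vectorized).
#' @return coverage fraction(s).
#' @export
coverage_from_spending <- function(cf, spending) {
  if (any(spending < 0)) stop("spending must be non-negative", call. = FALSE)
  if (cf$form == "unit_cost_logistic") {
    scale <- cf$saturation * cf$target_pop_size * cf$unit_cost
    cf$saturation * tanh(spending / scale)
  } else {
    cf$L / (1 + exp(-cf$k * (spending - cf$S0)))
  }
}

#' Annual spending required to reach a coverage level
#'
#' Exact inverse of [coverage_from_spending()] on the open coverage range.
#'
#' @param cf a `cost_function`.
#' @param coverage target coverage fraction, in `[0, saturation)`.
#' @return annual spending in USD.
#' @export
spending_from_coverage <- function(cf, coverage) {
  if (cf$form == "unit_cost_logistic") {
    if (any(coverage < 0) || any(coverage >= cf$saturation)) {
      stop("unreachable coverage: must lie in [0, saturation)", call. = FALSE)
    }
    scale <- cf$saturation * cf$target_pop_size * cf$unit_cost
    scale * atanh(coverage / cf$saturation)
  } else {
    if (any(coverage <= 0) || any(coverage >= cf$L)) {
      stop("unreachable coverage: must lie in (0, L)", call. = FALSE)
    }
    cf$S0 - log(cf$L / coverage - 1) / cf$k
  }
}

#' Fit a 3-parameter logistic cost function to expenditure data
#'
#' Least-squares fit of `coverage = L / (1 + exp(-k (S - S0)))` to observed
#' (spending, coverage) points, via Levenberg-Marquardt.
#'
#' @param points a data frame (or list) with numeric columns `spending` and
#'   `coverage`; at least three points.
#' @return a `cost_function` of form `fitted_logistic`, with `residual_norm`
#'   as a fit diagnostic.
#' @export
fit_cost_function <- function(points) {
  s <- points$spending
  cv <- points$coverage
  if (length(s) < 3) {
    stop("fitting the 3-parameter logistic requires at least 3 points",
         call. = FALSE)
  }
  if (length(unique(s)) < 3 || stats::sd(cv) == 0) {
    stop("cost-function fit failure: degenerate points", call. = FALSE)
  }
  start <- list(L = max(cv) * 1.05, k = 4 / max(diff(range(s)), 1e-9),
                S0 = stats::median(s))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cv ~ L / (1 + exp(-k * (s - S0))), start = start,
      lower = c(L = 1e-9, k = 1e-12, S0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop("cost-function fit failure: ", conditionMessage(e), call. = FALSE)
    })
  p <- coef(fit)
  structure(list(form = "fitted_logistic", L = unname(p["L"]),
                 k = unname(p["k"]), S0 = unname(p["S0"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "cost_function")
}

# ---- target populations and baseline spending -------------------------------

#' Target-population size for a program
#'
#' Uses the intervention's explicit `target_pop_size` when the databook
#' provides one (e.g. a campaign-dose denominator); otherwise derives the
#' size from the target rule: annual pregnancies are approximated by annual
#' births, age-band targets sum the band populations, and below-poverty
#' targets are scaled by the poverty fraction.
#'
#' @param db a databook.
#' @param name a program name.
#' @return the number of people in the program's target group.
#' @export
target_population_size <- function(db, name) {
  iv <- db$interventions[[name]]
  if (is.null(iv)) stop("unknown intervention: ", name, call. = FALSE)
  if (!is.null(iv$target_pop_size)) return(iv$target_pop_size)
  tp <- iv$target_population
  yr <- as.character(db$horizon$start_year)
  n <- 0
  if (isTRUE(tp$pregnant)) n <- n + db$demographics$annual_births[[yr]]
  if (length(tp$age_bands) > 0) {
    n <- n + sum(db$demographics$population_per_band[tp$age_bands])
  }
  if (identical(tp$poverty, "below")) {
    n <- n * db$demographics$poverty_fraction
  }
  n
}

#' Cost functions for every program in a databook
#'
#' @param db a databook.
#' @return a named list of `cost_function` objects.
#' @export
databook_cost_functions <- function(db) {
  out <- lapply(names(db$interventions), function(nm) {
    iv <- db$interventions[[nm]]
    cost_function(iv$unit_cost, target_population_size(db, nm),
                  iv$saturation)
  })
  setNames(out, names(db$interventions))
}

#' Estimate current annual spending on a program
#'
#' The rough published approximation: unit cost times the current number of
#' beneficiaries.
#'
#' @param unit_cost USD per beneficiary per year.
#' @param n_beneficiaries current number of beneficiaries covered.
#' @return annual spending in USD.
#' @export
estimate_current_spending <- function(unit_cost, n_beneficiaries) {
  stopifnot(unit_cost >= 0, n_beneficiaries >= 0)
  unit_cost * n_beneficiaries
}

#' Estimated current spending per program for a databook
#'
#' Applies [estimate_current_spending()] with beneficiaries = baseline
#' coverage times the target-population size.
#'
#' @param db a databook.
#' @return named annual USD spending over the programs.
#' @export
baseline_spending <- function(db) {
  vapply(names(db$interventions), function(nm) {
    iv <- db$interventions[[nm]]
    estimate_current_spending(
      iv$unit_cost, iv$baseline_coverage * target_population_size(db, nm))
  }, 0)
}

# round half away from zero (display convention for printed shares)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Spending shares of a budget allocation
#'
#' @param alloc named annual spending per program (USD).
#' @param percent_digits if non-`NULL`, return percentages rounded to this
#'   many decimal places, half away from zero.
#' @return fractions (or rounded percentages) per program.
#' @export
allocation_shares <- function(alloc, percent_digits = NULL) {
  total <- sum(alloc)
  if (!isTRUE(total > 0)) {
    stop("allocation_shares: total spending must be positive", call. = FALSE)
  }
  shares <- alloc / total
  if (is.null(percent_digits)) shares
  else round_half_up(100 * shares, percent_digits)
}
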