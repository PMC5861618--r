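# The deterministic monthly-timestep engine. State is a 16 x 5 count matrix
# (strata x age bands) with stunting category varying fastest within the 16
# strata. Each month applies, in order: births into the first band, deaths,
# then aging (a 1/width outflow from every band, with stunting reassigned at
# each band transition and graduates tallied from the last band).

# ---- relative-risk plumbing -------------------------------------------------

rr_stunting_for_cause <- function(effects, cause) {
  rr <- effects$stunting_mortality_rr[[cause]]
  if (is.null(rr)) setNames(rep(1, 4), stunting_categories()) else rr
}

rr_bf_for_cause <- function(effects, band, cause) {
  tabs <- effects$bf_mortality_rr[[band]]
  rr <- setNames(rep(1, 4), breastfeeding_categories())
  if (!is.null(tabs$all)) rr <- rr * tabs$all
  if (!is.null(tabs[[cause]])) rr <- rr * tabs[[cause]]
  rr
}

# Baseline-distribution-weighted mean of RR_stunting * RR_bf for one
# (band, cause): the normalization constant that keeps the population-average
# baseline rate equal to the calibrated rate.
rr_normalizer <- function(params, band, cause) {
  ef <- params$baseline$effects
  ws <- params$baseline$stunting_distribution[band, ]
  wb <- params$baseline$breastfeeding_distribution[band, ]
  sum(ws * rr_stunting_for_cause(ef, cause)) *
    sum(wb * rr_bf_for_cause(ef, band, cause))
}

#' Stratum- and cause-specific monthly mortality rates
#'
#' For each age band and applicable cause, the monthly death rate of stratum
#' (height-for-age s, breastfeeding b) is the calibrated band-level rate
#' times the two relative risks, divided by the baseline-distribution-
#' weighted mean of those relative risks (so that at the baseline risk
#' distribution the population-average rate equals the calibrated rate), and
#' times the intervention multiplier from [mortality_program_rr()].
#'
#' @param params calibrated model parameters from [calibrate()].
#' @param coverage a coverage vector.
#' @return a named list over age bands; each element a 16 x n_causes matrix
#'   of monthly rates (strata in engine order: stunting category fastest).
#' @export
mortality_rates <- function(params, coverage = baseline_coverage_vector_p(params)) {
  ef <- params$baseline$effects
  out <- list()
  for (a in seq_along(age_bands())) {
    band <- age_bands()[a]
    causes <- causes_of_death(band)
    m <- matrix(0, 16, length(causes),
                dimnames = list(NULL, causes))
    for (cz in causes) {
      rrs <- rr_stunting_for_cause(ef, cz)
      rrb <- rr_bf_for_cause(ef, band, cz)
      z <- params$Z[band, cz]
      pe <- mortality_program_rr(coverage, band, cz, ef)
      m[, cz] <- params$m[band, cz] *
        as.vector(outer(rrs, rrb)) / z * pe
    }
    out[[band]] <- m
  }
  out
}

# coverage vector stored with the params (the databook's baseline coverages)
baseline_coverage_vector_p <- function(params) {
  params$baseline$baseline_coverages
}

#' Diarrhea incidence by breastfeeding category
#'
#' Incidence in a band is the baseline episodes-per-child-month scaled by
#' the breastfeeding relative risk (normalized so the baseline-distribution
#' average equals the baseline incidence) and reduced by vitamin A coverage
#' in the bands of 6 months and older. `excess_diarrhea_episodes()` converts
#' this to the excess episodes accumulated over a band sojourn relative to
#' the age-appropriate reference practice (exclusive breastfeeding under 6
#' months, partial thereafter), floored at zero.
#'
#' @param params calibrated model parameters.
#' @param coverage a coverage vector.
#' @param band age band name.
#' @return named numeric over [breastfeeding_categories()].
#' @export
diarrhea_incidence <- function(params, coverage, band) {
  ef <- params$baseline$effects
  rr <- ef$diarrhea_rr_bf[[band]]
  wb <- params$baseline$breastfeeding_distribution[band, ]
  base <- params$baseline$diarrhea_incidence[[band]]
  inc <- base * rr / sum(wb * rr)
  if (band %in% c("6-11m", "12-23m", "24-59m")) {
    inc <- inc * (1 - coverage[["VAS"]] *
                    ef$program_effects$vas_diarrhea_incidence_reduction)
  }
  inc
}

#' @rdname diarrhea_incidence
#' @export
excess_diarrhea_episodes <- function(params, coverage, band) {
  inc <- diarrhea_incidence(params, coverage, band)
  ref <- if (band %in% c("<1m", "1-5m")) "exclusive" else "partial"
  pmax(inc - inc[[ref]], 0) * band_widths()[[band]]
}

# ---- transitions ------------------------------------------------------------

# Split a stunted probability into the four height-for-age categories using
# the within-group shape of the target band's baseline distribution.
stunting_split <- function(p_stunted, target_dist) {
  p_st <- stunted_fraction(target_dist)
  shape_no <- target_dist[c("normal", "mild")]
  shape_st <- target_dist[c("moderate", "severe")]
  shape_no <- if (sum(shape_no) > 0) shape_no / sum(shape_no) else c(1, 0)
  shape_st <- if (sum(shape_st) > 0) shape_st / sum(shape_st) else c(1, 0)
  c((1 - p_stunted) * shape_no, p_stunted * shape_st)
}

# Per-source-stratum stunted probability at entry to band_to, as a 16-vector
# over the source strata of band_from.
transition_stunted_prob <- function(params, coverage, a_from) {
  band_to <- age_bands()[a_from + 1]
  band_from <- age_bands()[a_from]
  ef <- params$baseline$effects
  o <- params$entry_odds[[band_to]]
  or_prev <- ifelse(stunted_mask(), ef$stunting_or_prev, 1)
  exc <- excess_diarrhea_episodes(params, coverage, band_from)
  or_dia <- rep(ef$diarrhea_or_stunting^exc, each = 4)
  prog <- stunting_program_or(coverage[["IYCF"]], coverage[["CFS"]],
                              params$baseline$poverty_fraction, band_to, ef)
  odds <- o * or_prev * or_dia * prog
  odds / (1 + odds)
}

# Breastfeeding distribution used for entrants to a band at the given
# coverage (baseline distribution, shifted by breastfeeding promotion in the
# under-6-month bands).
entry_bf_distribution <- function(params, coverage, band) {
  breastfeeding_shift(
    coverage[["BFP"]],
    params$baseline$breastfeeding_distribution[band, ],
    band,
    baseline_coverage = params$baseline$baseline_coverages[["BFP"]],
    effects = params$baseline$effects)
}

#' Reassign strata at an age-band transition
#'
#' For each child leaving `band_from`, the odds of being stunted on entry to
#' `band_to` are the calibrated band-entry odds times the prior-stunting
#' odds ratio (if the child was stunted), the diarrhea odds ratio raised to
#' the excess episodes accumulated over the band, and the feeding-program
#' multiplier. The stunted/non-stunted split is mapped onto the four
#' height-for-age categories proportionally to the target band's baseline
#' within-group shape, and the breastfeeding category is redrawn from the
#' target band's (intervention-adjusted) distribution. Counts are conserved.
#'
#' @param outgoing a 16-vector of counts leaving `band_from`.
#' @param params calibrated model parameters.
#' @param coverage a coverage vector.
#' @param band_from,band_to adjacent age band names.
#' @return a 16-vector of counts entering `band_to`.
#' @export
age_transition <- function(outgoing, params, coverage, band_from, band_to) {
  a <- match(band_from, age_bands())
  stopifnot(match(band_to, age_bands()) == a + 1)
  T <- transition_matrix(params, coverage, a)
  as.vector(T %*% outgoing)
}

# 16 x 16 matrix mapping band a strata to band a+1 strata (columns = source)
transition_matrix <- function(params, coverage, a_from) {
  band_to <- age_bands()[a_from + 1]
  p_st <- transition_stunted_prob(params, coverage, a_from)
  bf <- entry_bf_distribution(params, coverage, band_to)
  tdist <- params$baseline$stunting_distribution[band_to, ]
  T <- matrix(0, 16, 16)
  for (src in 1:16) {
    T[, src] <- as.vector(outer(stunting_split(p_st[src], tdist), bf))
  }
  T
}

# Per-birth entry distribution over the 16 strata of the first band.
birth_entry_vector <- function(params, coverage) {
  ef <- params$baseline$effects
  f <- birth_outcome_effect(coverage[["AMS"]], coverage[["BEP"]],
                            params$baseline$poverty_fraction,
                            params$baseline$birth_outcome_fractions, ef)
  o1 <- params$entry_odds[["<1m"]]
  odds <- o1 * ef$stunting_or_birth
  p_st <- sum(f * odds / (1 + odds))
  bf <- entry_bf_distribution(params, coverage, "<1m")
  tdist <- params$baseline$stunting_distribution["<1m", ]
  as.vector(outer(stunting_split(p_st, tdist), bf))
}

# ---- engine assembly --------------------------------------------------------

# Precompute everything that is constant over a projection at fixed coverage.
build_engine <- function(params, coverage, warn_cap = TRUE) {
  rates <- mortality_rates(params, coverage)
  r_tot <- lapply(rates, rowSums)
  capped <- FALSE
  for (a in seq_along(r_tot)) {
    over <- r_tot[[a]] > 0.99
    if (any(over)) {
      capped <- TRUE
      scl <- ifelse(over, 0.99 / r_tot[[a]], 1)
      rates[[a]] <- rates[[a]] * scl
      r_tot[[a]] <- pmin(r_tot[[a]], 0.99)
    }
  }
  if (capped && warn_cap) {
    warning("monthly mortality rate exceeded 0.99 in at least one stratum; ",
            "capped", call. = FALSE)
  }
  trans <- lapply(1:4, function(a) transition_matrix(params, coverage, a))
  list(rates = rates, r_tot = r_tot, trans = trans,
       entry = birth_entry_vector(params, coverage),
       widths = unname(band_widths()))
}

#' Initialize the population state from a databook
#'
#' Distributes each band's population over the 16 strata as the product of
#' the band's stunting and breastfeeding distributions (the two axes are
#' taken independent at initialization), with all cumulative tallies zero.
#'
#' @param db a validated databook.
#' @return an object of class `population_state`: a 16 x 5 count matrix plus
#'   a month index and cumulative tallies of deaths (by cause), graduates
#'   and births.
#' @export
initialize_state <- function(db) {
  v <- validate_databook(db)
  if (length(v) > 0) {
    stop("invalid databook:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  counts <- matrix(0, 16, 5)
  colnames(counts) <- age_bands()
  for (a in seq_along(age_bands())) {
    band <- age_bands()[a]
    counts[, a] <- db$demographics$population_per_band[[band]] *
      as.vector(outer(db$risks$stunting_distribution[band, ],
                      db$risks$breastfeeding_distribution[band, ]))
  }
  new_population_state(counts)
}

new_population_state <- function(counts, month_index = 0L) {
  structure(
    list(counts = counts, month_index = month_index,
         cumulative = list(
           deaths_by_cause = setNames(numeric(length(all_causes())),
                                      all_causes()),
           deaths_total = 0, graduates_total = 0,
           graduates_not_stunted = 0, births_total = 0)),
    class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> month", x$month_index, "\n")
  cat("  children:", format(round(sum(x$counts)), big.mark = ","),
      sprintf(" (stunted: %.1f%%)",
              100 * sum(x$counts[stunted_mask(), ]) / sum(x$counts)), "\n")
  cat("  cumulative deaths:", round(x$cumulative$deaths_total),
      " graduates:", round(x$cumulative$graduates_total),
      sprintf("(not stunted: %d)",
              round(x$cumulative$graduates_not_stunted)), "\n")
  invisible(x)
}

# One month of dynamics on the raw count matrix. Returns the updated counts
# plus the month's flows. Kept free of S3 overhead: run_projection calls it
# in a tight loop.
step_core <- function(counts, engine, births) {
  counts[, 1] <- counts[, 1] + births * engine$entry
  deaths_by_cause <- lapply(seq_len(5), function(a) {
    colSums(counts[, a] * engine$rates[[a]])
  })
  for (a in seq_len(5)) {
    counts[, a] <- counts[, a] * (1 - engine$r_tot[[a]])
  }
  # the living population this month, used for prevalence summaries (the
  # post-aging snapshot leaves the width-1 neonatal band empty)
  mid <- counts
  # outflows are computed from the post-death counts before any transfers
  # are added, so children cannot pass through two bands in one month
  outs <- lapply(seq_len(5), function(a) counts[, a] / engine$widths[a])
  for (a in seq_len(5)) counts[, a] <- counts[, a] - outs[[a]]
  for (a in 1:4) {
    counts[, a + 1] <- counts[, a + 1] + engine$trans[[a]] %*% outs[[a]]
  }
  grad <- outs[[5]]
  list(counts = counts, mid = mid, deaths_by_cause = deaths_by_cause,
       graduates = sum(grad),
       graduates_not_stunted = sum(grad[!stunted_mask()]))
}

#' Advance the population by one month
#'
#' Applies, in order: births into the first band (with birth-outcome-driven
#' entry stunting odds and the under-6-month breastfeeding distribution),
#' mortality per [mortality_rates()], then aging (a `1/width` outflow from
#' every band through [age_transition()], with graduates from the last band
#' tallied by the stunted predicate). The person ledger is exact:
#' the change in total children equals births minus deaths minus graduates.
#'
#' @param state a `population_state`.
#' @param params calibrated model parameters.
#' @param coverage a coverage vector.
#' @param births number of births entering this month.
#' @return the updated `population_state`.
#' @export
step_month <- function(state, params, coverage, births) {
  engine <- build_engine(params, coverage)
  res <- step_core(state$counts, engine, births)
  if (any(res$counts < 0)) {
    stop("engine error: negative count after monthly update", call. = FALSE)
  }
  cum <- state$cumulative
  for (a in seq_len(5)) {
    dc <- res$deaths_by_cause[[a]]
    cum$deaths_by_cause[names(dc)] <- cum$deaths_by_cause[names(dc)] + dc
    cum$deaths_total <- cum$deaths_total + sum(dc)
  }
  cum$graduates_total <- cum$graduates_total + res$graduates
  cum$graduates_not_stunted <- cum$graduates_not_stunted +
    res$graduates_not_stunted
  cum$births_total <- cum$births_total + births
  structure(list(counts = res$counts,
                 month_index = state$month_index + 1L,
                 cumulative = cum),
            class = "population_state")
}

# monthly births vector over the projection, from the databook's annual
# series (spread uniformly over each year's 12 months)
monthly_births_series <- function(db, months) {
  if (months == 0) return(numeric(0))
  yrs <- db$horizon$start_year + (seq_len(months) - 1) %/% 12
  ab <- db$demographics$annual_births
  if (!all(as.character(yrs) %in% names(ab))) {
    stop("annual_births series does not cover the projection horizon",
         call. = FALSE)
  }
  unname(ab[as.character(yrs)] / 12)
}

#' Project the population over a horizon
#'
#' Iterates [step_month()] from the databook's initial state at a fixed
#' coverage vector, with annual births spread uniformly over months.
#'
#' @param db a databook.
#' @param params calibrated model parameters from [calibrate()].
#' @param coverage a coverage vector; defaults to the databook's baseline
#'   coverages.
#' @param months projection length; defaults to the databook horizon.
#' @param state optional starting state (defaults to
#'   [initialize_state()]`(db)`).
#' @return an object of class `trajectory`: a monthly summary data frame
#'   (population, stunting prevalence, deaths, cumulative graduates alive
#'   and not stunted), cumulative deaths by cause, the final per-band
#'   stunting prevalence and the final state.
#' @export
run_projection <- function(db, params, coverage = baseline_coverage_vector(db),
                           months = NULL, state = NULL) {
  if (is.null(months)) {
    months <- 12L * (db$horizon$end_year - db$horizon$start_year + 1L)
  }
  if (is.null(state)) state <- initialize_state(db)
  engine <- build_engine(params, coverage)
  births <- monthly_births_series(db, months)
  counts <- state$counts
  mid <- state$counts
  cum_deaths <- 0
  cum_grad <- 0
  cum_grad_ns <- 0
  cum_births <- 0
  deaths_by_cause <- setNames(numeric(length(all_causes())), all_causes())
  sm <- matrix(0, months, 7)
  colnames(sm) <- c("month", "total_pop", "stunting_prevalence",
                    "deaths", "cum_deaths", "cum_graduates",
                    "cum_graduates_not_stunted")
  for (t in seq_len(months)) {
    res <- step_core(counts, engine, births[t])
    counts <- res$counts
    d <- 0
    for (a in seq_len(5)) {
      dc <- res$deaths_by_cause[[a]]
      deaths_by_cause[names(dc)] <- deaths_by_cause[names(dc)] + dc
      d <- d + sum(dc)
    }
    cum_deaths <- cum_deaths + d
    cum_grad <- cum_grad + res$graduates
    cum_grad_ns <- cum_grad_ns + res$graduates_not_stunted
    cum_births <- cum_births + births[t]
    sm[t, ] <- c(t, sum(res$mid),
                 sum(res$mid[stunted_mask(), ]) / sum(res$mid),
                 d, cum_deaths, cum_grad, cum_grad_ns)
    mid <- res$mid
  }
  final_state <- new_population_state(counts, months)
  final_state$cumulative <- list(
    deaths_by_cause = deaths_by_cause, deaths_total = cum_deaths,
    graduates_total = cum_grad, graduates_not_stunted = cum_grad_ns,
    births_total = cum_births)
  band_pop <- if (months > 0) mid else state$counts
  band_prev <- colSums(band_pop[stunted_mask(), , drop = FALSE]) /
    colSums(band_pop)
  structure(
    list(summary = as.data.frame(sm), months = months,
         births = births,
         deaths_by_cause = deaths_by_cause,
         band_stunting_prevalence = setNames(band_prev, age_bands()),
         cumulative = final_state$cumulative,
         final_state = final_state,
         coverage = coverage),
    class = "trajectory")
}

#' Under-5 mortality rate of a projection
#'
#' Deaths per 1000 live births over the trajectory. Because the initial
#' state is a cross-sectional population snapshot rather than the engine's
#' own stationary orbit, the first months carry a small initialization
#' transient; a burn-in (default 60 months, one full residence time) drops
#' it so the stationary rate is measured.
#'
#' @param traj a trajectory from [run_projection()].
#' @param burn_in_months months to discard before measuring.
#' @return deaths per 1000 live births.
#' @export
projected_u5mr <- function(traj, burn_in_months = 60) {
  keep <- traj$summary$month > burn_in_months
  stopifnot(any(keep), sum(traj$births[keep]) > 0)
  1000 * sum(traj$summary$deaths[keep]) / sum(traj$births[keep])
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$months, "months\n")
  if (x$months > 0) {
    last <- x$summary[nrow(x$summary), ]
    cat(sprintf("  final stunting prevalence: %.1f%%\n",
                100 * last$stunting_prevalence))
    cat(sprintf("  cumulative deaths: %s; graduates alive & not stunted: %s\n",
                format(round(last$cum_deaths), big.mark = ","),
                format(round(last$cum_graduates_not_stunted),
                       big.mark = ",")))
  }
  invisible(x)
}

#' Export a trajectory
#'
#' `trajectory_long()` returns the monthly summary in tidy long form
#' (month, metric, value); `write_trajectory_csv()` writes it as UTF-8 CSV
#' with a header row.
#'
#' @param traj a trajectory.
#' @return a data frame in long form.
#' @export
trajectory_long <- function(traj) {
  s <- traj$summary
  metrics <- setdiff(colnames(s), "month")
  out <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(month = s$month, metric = m, value = s[[m]])
  }))
  out[order(out$month, out$metric), , drop = FALSE]
}

#' @param path output CSV path.
#' @rdname trajectory_long
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(trajectory_long(traj), path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
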