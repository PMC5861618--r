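# Calibration: choose band-level monthly mortality rates and band-entry
# stunting odds so that, at the databook's baseline coverages and baseline
# risk distributions, the engine reproduces the observed under-5 mortality
# rate (and its neonatal share) and the observed per-band stunting
# distribution. Because the within-band dynamics are linear and memoryless,
# deaths per band entrant have a closed form, which makes the calibration
# fast and exact.

#' Closed-form constant-hazard solvers
#'
#' `monthly_hazard_for_total()` solves `1 - (1 - m)^months = q` for the
#' constant monthly rate `m` that yields a cumulative death probability `q`
#' over a fixed number of months. `band_advance_probability()` is the
#' probability that a child entering a band of width `w` months leaves it
#' alive under the engine's death-then-1/w-outflow monthly update with
#' constant monthly rate `m`.
#'
#' @param q cumulative death probability.
#' @param months exposure in months.
#' @return a monthly rate (or probability).
#' @export
monthly_hazard_for_total <- function(q, months) {
  stopifnot(q >= 0, q < 1, months > 0)
  1 - (1 - q)^(1 / months)
}

#' @param m constant monthly mortality rate.
#' @param w band width in months.
#' @rdname monthly_hazard_for_total
#' @export
band_advance_probability <- function(m, w) {
  ((1 - m) / w) / (1 - (1 - m) * (1 - 1 / w))
}

# ---- params object ----------------------------------------------------------

new_model_params <- function(db, m, entry_odds) {
  baseline <- list(
    stunting_distribution = db$risks$stunting_distribution,
    breastfeeding_distribution = db$risks$breastfeeding_distribution,
    diarrhea_incidence = db$risks$diarrhea_incidence,
    birth_outcome_fractions = db$demographics$birth_outcome_fractions,
    poverty_fraction = db$demographics$poverty_fraction,
    baseline_coverages = baseline_coverage_vector(db),
    effects = db$effects)
  params <- structure(
    list(m = m, entry_odds = entry_odds, baseline = baseline,
         Z = NULL, diagnostics = NULL),
    class = "model_params")
  Z <- matrix(1, 5, length(all_causes()),
              dimnames = list(age_bands(), all_causes()))
  for (band in age_bands()) {
    for (cz in causes_of_death(band)) {
      Z[band, cz] <- rr_normalizer(params, band, cz)
    }
  }
  params$Z <- Z
  params
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> calibrated monthly mortality and entry-stunting odds\n")
  d <- x$diagnostics
  if (!is.null(d)) {
    cat(sprintf("  simulated U5MR: %.3f per 1000 (target %.3f)\n",
                d$u5mr_simulated, d$u5mr_target))
    cat(sprintf("  simulated neonatal share: %.4f (target %.4f)\n",
                d$neonatal_share_simulated, d$neonatal_share_target))
    cat(sprintf("  max band-entry stunting error: %.3g (absolute)\n",
                d$max_entry_stunting_error))
  }
  invisible(x)
}

# ---- closed-form cohort propagation ----------------------------------------

# Follow one birth cohort through the engine's monthly update. Within a band
# the update is diagonal (deaths then a 1/w outflow), so total exposure,
# deaths and advancers per entrant have closed forms. Returns deaths by band
# and cause, the pre-transition advancer mix per band and the entry vector
# of each band, all per live birth.
cohort_flows <- function(engine) {
  v <- engine$entry
  entries <- list(v)
  deaths_band <- numeric(5)
  deaths_by_cause <- setNames(numeric(length(all_causes())), all_causes())
  deaths_cause_band <- vector("list", 5)
  advancers <- vector("list", 5)
  for (a in seq_len(5)) {
    w <- engine$widths[a]
    r <- engine$r_tot[[a]]
    X <- v / (1 - (1 - r) * (1 - 1 / w))
    dc <- colSums(X * engine$rates[[a]])
    deaths_by_cause[names(dc)] <- deaths_by_cause[names(dc)] + dc
    deaths_cause_band[[a]] <- dc
    deaths_band[a] <- sum(dc)
    adv <- (1 / w) * (1 - r) * X
    advancers[[a]] <- adv
    if (a < 5) {
      v <- as.vector(engine$trans[[a]] %*% adv)
      entries[[a + 1]] <- v
    }
  }
  list(deaths_band = deaths_band, deaths_by_cause = deaths_by_cause,
       deaths_cause_band = deaths_cause_band,
       advancers = advancers, entries = entries,
       graduates = sum(advancers[[5]]))
}

# solve o in sum(w * sigma(o * mult)) = p_target (weights need not sum to 1;
# they are normalized)
solve_entry_odds <- function(weights, mult, p_target) {
  w <- weights / sum(weights)
  f <- function(lo) sum(w * plogis(lo + log(mult))) - p_target
  stopifnot(p_target > 0, p_target < 1)
  uniroot(f, c(-40, 40), tol = 1e-13)$root |> exp()
}

# entry odds for every band given current mortality rates, solved
# sequentially from births upward so each band reproduces its databook
# stunted fraction at baseline coverage
solve_all_entry_odds <- function(db, params, coverage) {
  ef <- db$effects
  p_target <- stunted_fraction(db$risks$stunting_distribution)
  f_birth <- birth_outcome_effect(coverage[["AMS"]], coverage[["BEP"]],
                                  db$demographics$poverty_fraction,
                                  db$demographics$birth_outcome_fractions, ef)
  odds <- params$entry_odds
  odds[["<1m"]] <- solve_entry_odds(f_birth, ef$stunting_or_birth,
                                    p_target[["<1m"]])
  params$entry_odds <- odds
  for (a in 1:4) {
    flows <- cohort_flows(build_engine(params, coverage))
    adv <- flows$advancers[[a]]
    band_to <- age_bands()[a + 1]
    or_prev <- ifelse(stunted_mask(), ef$stunting_or_prev, 1)
    exc <- excess_diarrhea_episodes(params, coverage, age_bands()[a])
    or_dia <- rep(ef$diarrhea_or_stunting^exc, each = 4)
    prog <- stunting_program_or(coverage[["IYCF"]], coverage[["CFS"]],
                                db$demographics$poverty_fraction, band_to, ef)
    odds[[band_to]] <- solve_entry_odds(adv, or_prev * or_dia * prog,
                                        p_target[[band_to]])
    params$entry_odds <- odds
  }
  params
}

# set the band x cause baseline rate matrix from hazard scales: named causes
# proportional to the cause fractions, the "other" cause given explicitly
rate_matrix <- function(db, h_neo_named, other_neo, h_post_named, other_post) {
  m <- matrix(0, 5, length(all_causes()),
              dimnames = list(age_bands(), all_causes()))
  f_neo <- db$mortality$cause_fractions_neonatal
  f_post <- db$mortality$cause_fractions_postneonatal
  named_neo <- setdiff(names(f_neo), "other")
  named_post <- setdiff(names(f_post), "other")
  m["<1m", named_neo] <- h_neo_named * f_neo[named_neo]
  m["<1m", "other"] <- other_neo
  for (band in age_bands()[2:5]) {
    m[band, named_post] <- h_post_named * f_post[named_post]
    m[band, "other"] <- other_post
  }
  m
}

#' Calibrate the model to a databook
#'
#' Determines (a) per-band cause-specific baseline monthly mortality rates
#' such that the simulated under-5 deaths per 1000 live births match the
#' databook's U5MR, with the observed neonatal share, at baseline coverages
#' and baseline risk distributions; and (b) band-entry stunting odds such
#' that band-entry stunting reproduces the databook's per-band stunting
#' distribution under the same conditions.
#'
#' Named-cause rates are proportional to the databook's cause-of-death
#' fractions; the residual needed to match total mortality is absorbed by
#' the "other" cause. A negative residual (inputs inconsistent) is an
#' error. Mortality is split between the neonatal band and a constant
#' post-neonatal monthly hazard shared by the four older bands.
#'
#' @param db a validated databook.
#' @param verbose log a note when placeholder effect sizes are in use.
#' @return calibrated `model_params` with a `diagnostics` block (simulated
#'   vs target U5MR, neonatal share, per-band entry-stunting error).
#' @export
calibrate <- function(db, verbose = TRUE) {
  v <- validate_databook(db)
  if (length(v) > 0) {
    stop("invalid databook:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  if (verbose && isTRUE(db$effects$placeholder)) {
    message("calibrate: placeholder effect sizes are in use; ",
            "supply setting-specific values for real analyses")
  }
  coverage <- baseline_coverage_vector(db)
  q5 <- db$mortality$u5mr / 1000
  q_neo <- q5 * db$mortality$neonatal_share
  q_post <- q5 - q_neo

  # closed-form starting hazards: the neonatal band has width 1 (per-entrant
  # death probability equals its monthly rate); the post-neonatal bands
  # share a constant monthly hazard solved from the band-advance closed form
  h_neo <- q_neo
  post_gap <- function(h) {
    surv <- prod(vapply(2:5, function(a) {
      band_advance_probability(h, unname(band_widths())[a])
    }, 0))
    (1 - q_neo) * (1 - surv) - q_post
  }
  h_post <- if (q_post > 0) uniroot(post_gap, c(0, 0.5), tol = 1e-14)$root else 0

  f_other_neo <- db$mortality$cause_fractions_neonatal[["other"]]
  f_other_post <- db$mortality$cause_fractions_postneonatal[["other"]]
  params <- new_model_params(
    db, rate_matrix(db, h_neo, h_neo * f_other_neo,
                    h_post, h_post * f_other_post),
    setNames(rep(0.5, 5), age_bands()))

  # hazard state: named-cause scale and residual "other" rate per group
  hn <- h_neo
  on <- h_neo * f_other_neo
  hp <- h_post
  op <- h_post * f_other_post
  target_named_neo <- q_neo * (1 - f_other_neo)
  target_named_post <- q_post * (1 - f_other_post)
  named_neo <- setdiff(causes_of_death("<1m"), "other")
  named_post <- setdiff(causes_of_death("1-5m"), "other")

  flows_at <- function(hn, on, hp, op) {
    params$m <- rate_matrix(db, hn, on, hp, op)
    # root brackets probe hazards far above the target scale; the engine
    # caps those probes, which is expected rather than noteworthy here
    cohort_flows(build_engine(params, coverage, warn_cap = FALSE))
  }
  solve1 <- function(f, lower, upper, target) {
    # monotone scalar root; returns 0 when the target is already met at 0
    if (target <= 0) return(0)
    uniroot(function(x) f(x) - target, c(lower, upper), tol = 1e-14,
            extendInt = "upX")$root
  }

  for (pass in 1:2) {
    params <- solve_all_entry_odds(db, params, coverage)
    # alternate: named-cause scales hit the named share of the mortality
    # target; the "other" rate absorbs the residual up to the total
    for (it in 1:2) {
      hn <- solve1(function(h) {
        sum(flows_at(h, on, hp, op)$deaths_cause_band[[1]][named_neo])
      }, 0, 0.9, target_named_neo)
      resid_neo <- function(o) {
        flows_at(hn, o, hp, op)$deaths_band[1]
      }
      if (resid_neo(0) > q_neo * (1 + 1e-9) + 1e-15) {
        stop("calibration failure: residual 'other' cause rate is negative ",
             "in band <1m (named-cause mortality already exceeds the ",
             "neonatal target; inputs inconsistent)", call. = FALSE)
      }
      on <- if (resid_neo(0) >= q_neo) 0 else solve1(resid_neo, 0, 0.9,
                                                     q_neo)
      hp <- solve1(function(h) {
        fl <- flows_at(hn, on, h, op)
        sum(vapply(fl$deaths_cause_band[2:5],
                   function(dc) sum(dc[named_post]), 0))
      }, 0, 0.9, target_named_post)
      resid_post <- function(o) {
        sum(flows_at(hn, on, hp, o)$deaths_band[2:5])
      }
      if (resid_post(0) > q_post * (1 + 1e-9) + 1e-15) {
        stop("calibration failure: residual 'other' cause rate is negative ",
             "in bands 1-59m (named-cause mortality already exceeds the ",
             "post-neonatal target; inputs inconsistent)", call. = FALSE)
      }
      op <- if (resid_post(0) >= q_post) 0 else solve1(resid_post, 0, 0.9,
                                                       q_post)
    }
    params$m <- rate_matrix(db, hn, on, hp, op)
  }

  flows <- cohort_flows(build_engine(params, coverage))
  q5_sim <- sum(flows$deaths_band)
  entry_err <- vapply(seq_len(5), function(a) {
    v <- flows$entries[[a]]
    abs(sum(v[stunted_mask()]) / sum(v) -
          stunted_fraction(db$risks$stunting_distribution)[a])
  }, 0)
  params$diagnostics <- list(
    u5mr_target = db$mortality$u5mr,
    u5mr_simulated = 1000 * q5_sim,
    neonatal_share_target = db$mortality$neonatal_share,
    neonatal_share_simulated = flows$deaths_band[1] / q5_sim,
    deaths_by_cause_per_1000 = 1000 * flows$deaths_by_cause,
    max_entry_stunting_error = max(entry_err),
    placeholder_effects = isTRUE(db$effects$placeholder))
  params
}

# Stationary population profile implied by calibrated parameters: person-
# months of exposure per band per birth, times the monthly birth flow.
# Used by the fixture generators so that projections start at equilibrium.
stationary_population <- function(params, coverage, monthly_births) {
  engine <- build_engine(params, coverage)
  v <- engine$entry
  pop <- numeric(5)
  for (a in seq_len(5)) {
    w <- engine$widths[a]
    r <- engine$r_tot[[a]]
    X <- v / (1 - (1 - r) * (1 - 1 / w))
    pop[a] <- sum(X)
    if (a < 5) {
      v <- as.vector(engine$trans[[a]] %*% ((1 / w) * (1 - r) * X))
    }
  }
  setNames(pop * monthly_births, age_bands())
}
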