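# Translation of program coverages into parameter modifications. Coverage is
# always population coverage of the program's own target group (so BEP and
# CFS coverages are measured among the below-poverty stratum they target).

#' Coverage vector helpers
#'
#' A coverage vector is a named numeric vector over the six programs with
#' entries in `[0, 1]`. `baseline_coverage_vector()` extracts the databook's
#' current coverages; `coverage_vector()` builds one from named arguments
#' with unspecified programs at zero.
#'
#' @param db a databook.
#' @return a named numeric vector over [intervention_names()].
#' @export
baseline_coverage_vector <- function(db) {
  cov <- setNames(numeric(length(intervention_names())),
                  intervention_names())
  have <- vapply(db$interventions, `[[`, 0, "baseline_coverage")
  cov[names(have)] <- have
  cov
}

#' @param ... named coverages, e.g. `IYCF = 0.8`.
#' @rdname baseline_coverage_vector
#' @export
coverage_vector <- function(...) {
  cov <- setNames(numeric(length(intervention_names())),
                  intervention_names())
  args <- list(...)
  stopifnot(all(names(args) %in% intervention_names()))
  cov[names(args)] <- unlist(args)
  if (any(cov < 0 | cov > 1)) stop("coverages must lie in [0,1]")
  cov
}

#' Birth-outcome shift from antenatal supplementation programs
#'
#' Antenatal micronutrient supplementation (AMS) reaches a fraction
#' `cov_ams` of all pregnancies; balanced energy-protein supplementation
#' (BEP) reaches a fraction `cov_bep` of below-poverty pregnancies, i.e.
#' `cov_bep * poverty_fraction` of all pregnancies. Within a covered
#' pregnancy each program multiplies the odds of the small-for-gestational-
#' age outcomes by its odds ratio (odds taken against the remaining
#' outcomes, then renormalized); a pregnancy covered by both gets the
#' product of the two odds ratios. Coverage overlap is assumed independent,
#' and the returned fractions are the mixture over the four coverage
#' combinations.
#'
#' @param cov_ams,cov_bep program coverages of their target groups.
#' @param poverty_fraction fraction of pregnancies below the poverty line.
#' @param baseline_outcomes named fractions over [birth_outcomes()].
#' @param effects effect-size table (for `ams_birth_or`, `bep_birth_or`).
#' @return modified birth-outcome fractions (sum 1).
#' @export
birth_outcome_effect <- function(cov_ams, cov_bep, poverty_fraction,
                                 baseline_outcomes,
                                 effects = default_effect_sizes()) {
  pe <- effects$program_effects
  reach_bep <- cov_bep * poverty_fraction
  combos <- list(
    list(w = (1 - cov_ams) * (1 - reach_bep), or = 1),
    list(w = cov_ams * (1 - reach_bep), or = pe$ams_birth_or),
    list(w = (1 - cov_ams) * reach_bep, or = pe$bep_birth_or),
    list(w = cov_ams * reach_bep, or = pe$ams_birth_or * pe$bep_birth_or))
  sga <- c("term_sga", "preterm_sga")
  out <- setNames(numeric(4), birth_outcomes())
  for (cb in combos) {
    if (cb$w == 0) next
    f <- baseline_outcomes
    f[sga] <- f[sga] * cb$or
    out <- out + cb$w * f / sum(f)
  }
  out
}

#' Exclusive-breastfeeding shift from breastfeeding promotion
#'
#' For the under-6-month bands, the exclusive-breastfeeding prevalence moves
#' linearly with coverage around the anchor point (baseline coverage,
#' baseline prevalence): full coverage attains
#' `bfp_efficacy * (bfp_max_exclusive - baseline)` of the remaining headroom
#' above the baseline prevalence, and coverage below baseline declines along
#' the same slope (floored at zero). Probability mass is drawn from (or
#' returned to) the predominant/partial/none categories proportionally to
#' their baseline shares.
#'
#' @param cov_bfp coverage of the breastfeeding-promotion program.
#' @param baseline_bf_distribution named fractions over
#'   [breastfeeding_categories()].
#' @param band age band; only `<1m` and `1-5m` are affected.
#' @param baseline_coverage the program's current coverage (the anchor).
#' @param effects effect-size table.
#' @return a modified breastfeeding distribution (sum 1).
#' @export
breastfeeding_shift <- function(cov_bfp, baseline_bf_distribution, band,
                                baseline_coverage = 0,
                                effects = default_effect_sizes()) {
  if (!band %in% c("<1m", "1-5m")) return(baseline_bf_distribution)
  pe <- effects$program_effects
  e0 <- baseline_bf_distribution[["exclusive"]]
  emax <- pe$bfp_max_exclusive
  if (baseline_coverage >= 1 || emax <= e0) return(baseline_bf_distribution)
  slope <- pe$bfp_efficacy * (emax - e0) / (1 - baseline_coverage)
  e1 <- min(max(e0 + (cov_bfp - baseline_coverage) * slope, 0), emax)
  out <- baseline_bf_distribution
  others <- setdiff(breastfeeding_categories(), "exclusive")
  if (sum(baseline_bf_distribution[others]) > 0) {
    out[others] <- baseline_bf_distribution[others] *
      (1 - e1) / sum(baseline_bf_distribution[others])
  }
  out[["exclusive"]] <- e1
  out / sum(out)
}

#' Stunting odds-ratio multiplier from feeding programs
#'
#' Applies to entry into the 6-11 and 12-23 month bands. Above the poverty
#' line, IYCF education alone lowers stunting odds; below the poverty line,
#' education cannot help unless complementary food is also provided, so only
#' CFS (which bundles the education component) has an effect there. The
#' returned multiplier is the population-average odds multiplier across the
#' two poverty strata.
#'
#' @param cov_iycf coverage of IYCF education among all 6-23-month children.
#' @param cov_cfs coverage of complementary food provision among its
#'   below-poverty target group.
#' @param poverty_fraction fraction of children below the poverty line.
#' @param band age band; bands outside 6-23 months return 1.
#' @param effects effect-size table.
#' @return a scalar odds-ratio multiplier in `(0, 1]`.
#' @export
stunting_program_or <- function(cov_iycf, cov_cfs, poverty_fraction, band,
                                effects = default_effect_sizes()) {
  if (!band %in% c("6-11m", "12-23m")) return(1)
  pe <- effects$program_effects
  q <- poverty_fraction
  above <- 1 - cov_iycf * (1 - pe$iycf_stunting_or)
  below <- 1 - cov_cfs * (1 - pe$cfs_stunting_or)
  mult <- (1 - q) * above + q * below
  min(max(mult, 1e-12), 1)
}

#' Mortality-rate multiplier from intervention coverage
#'
#' Vitamin A supplementation multiplies diarrhea-cause mortality in the
#' bands of 6 months and older by `1 - cov * vas_diarrhea_mortality_
#' reduction`; IYCF multiplies all-cause mortality in the 6-23-month bands
#' by `1 - cov * (1 - iycf_mortality_rr)`. Multipliers combine
#' multiplicatively and are clipped to `(0, 1]`.
#'
#' @param coverage a coverage vector (see [coverage_vector()]).
#' @param band age band.
#' @param cause cause of death.
#' @param effects effect-size table.
#' @return a scalar multiplier in `(0, 1]`.
#' @export
mortality_program_rr <- function(coverage, band, cause,
                                 effects = default_effect_sizes()) {
  pe <- effects$program_effects
  mult <- 1
  if (band %in% c("6-11m", "12-23m", "24-59m") && cause == "diarrhea") {
    mult <- mult * (1 - coverage[["VAS"]] * pe$vas_diarrhea_mortality_reduction)
  }
  if (band %in% c("6-11m", "12-23m")) {
    mult <- mult * (1 - coverage[["IYCF"]] * (1 - pe$iycf_mortality_rr))
  }
  min(max(mult, 1e-12), 1)
}
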