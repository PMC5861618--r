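# Shared fixtures, cached so the (fast, but not free) generator and
# calibration run once per test session.

.fixtures <- new.env(parent = emptyenv())

demo_db <- function() {
  if (is.null(.fixtures$db)) .fixtures$db <- generate_demo_databook(1)
  .fixtures$db
}

demo_params <- function() {
  if (is.null(.fixtures$params)) {
    .fixtures$params <- calibrate(demo_db(), verbose = FALSE)
  }
  .fixtures$params
}

demo_problem <- function() {
  if (is.null(.fixtures$problem)) {
    .fixtures$problem <- optimization_problem(demo_db(), demo_params())
  }
  .fixtures$problem
}

demo_regions <- function() {
  if (is.null(.fixtures$regions)) {
    .fixtures$regions <- generate_region_fixtures(1)
  }
  .fixtures$regions
}

# lighter optimizer settings for tests that exercise full-model optimization
light_ctrl <- function(seed = 1, ...) {
  utils::modifyList(
    list(max_evals = 400L, stall_window = 120L, restarts = 2L, seed = seed),
    list(...))
}

# A small, fully synthetic databook with simple overridable blocks, used
# for closed-form and property tests. Distributions are deliberately plain.
toy_databook <- function(u5mr = 40, neonatal_share = 0.5,
                         births = 12000, poverty = 0.3,
                         effects = default_effect_sizes(),
                         stunting = NULL, breastfeeding = NULL,
                         coverages = c(AMS = 0, BEP = 0, BFP = 0,
                                       IYCF = 0, CFS = 0, VAS = 0),
                         cause_neo = NULL, cause_post = NULL,
                         diarrhea = c(0.1, 0.2, 0.3, 0.25, 0.1)) {
  bands <- age_bands()
  if (is.null(stunting)) {
    stunting <- matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 5), 5, 4,
                       dimnames = list(bands, stunting_categories()))
  }
  if (is.null(breastfeeding)) {
    breastfeeding <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), each = 5), 5, 4,
                            dimnames = list(bands,
                                            breastfeeding_categories()))
  }
  if (is.null(cause_neo)) {
    cause_neo <- setNames(c(0.05, 0.1, 0.05, 0.2, 0.15, 0.25, 0.2),
                          causes_of_death("<1m"))
  }
  if (is.null(cause_post)) {
    cause_post <- setNames(c(0.15, 0.25, 0.05, 0.55), causes_of_death("1-5m"))
  }
  yrs <- 2016:2030
  demographics <- list(
    population_per_band = setNames(births / 12 * unname(band_widths()),
                                   bands),
    annual_births = setNames(rep(births, length(yrs)), yrs),
    birth_outcome_fractions = setNames(c(0.6, 0.25, 0.1, 0.05),
                                       birth_outcomes()),
    poverty_fraction = poverty)
  mortality <- list(u5mr = u5mr, neonatal_share = neonatal_share,
                    cause_fractions_neonatal = cause_neo,
                    cause_fractions_postneonatal = cause_post)
  risks <- list(stunting_distribution = stunting,
                breastfeeding_distribution = breastfeeding,
                diarrhea_incidence = setNames(diarrhea, bands))
  ivs <- nutriopt:::demo_interventions(scale = births / 3e6,
                                       coverages = coverages)
  databook("toyland", demographics, mortality, risks, ivs, effects,
           list(start_year = 2016L, end_year = 2030L))
}

# randomized valid databook for property tests (seeded by the caller)
random_databook <- function() {
  rdist <- function(n) {
    g <- rexp(n) + 0.05
    g / sum(g)
  }
  stunting <- t(replicate(5, rdist(4)))
  dimnames(stunting) <- list(age_bands(), stunting_categories())
  breastfeeding <- t(replicate(5, rdist(4)))
  dimnames(breastfeeding) <- list(age_bands(), breastfeeding_categories())
  cause_neo <- setNames(rdist(7), causes_of_death("<1m"))
  cause_neo["other"] <- cause_neo[["other"]] + 0.5
  cause_neo <- cause_neo / sum(cause_neo)
  cause_post <- setNames(rdist(4), causes_of_death("1-5m"))
  cause_post["other"] <- cause_post[["other"]] + 0.5
  cause_post <- cause_post / sum(cause_post)
  toy_databook(u5mr = runif(1, 20, 80),
               neonatal_share = runif(1, 0.3, 0.7),
               births = runif(1, 5000, 50000),
               poverty = runif(1, 0.1, 0.5),
               stunting = stunting, breastfeeding = breastfeeding,
               coverages = c(AMS = runif(1, 0, 0.5), BEP = runif(1, 0, 0.5),
                             BFP = runif(1, 0, 0.8), IYCF = runif(1, 0, 0.8),
                             CFS = runif(1, 0, 0.5), VAS = runif(1, 0, 0.8)),
               cause_neo = cause_neo, cause_post = cause_post,
               diarrhea = runif(5, 0.05, 0.4))
}
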