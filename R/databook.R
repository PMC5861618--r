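# The databook is the single input document for one region: demographics,
# mortality, risk-factor distributions, intervention specifications and
# effect sizes. On disk it is a YAML document; in R it is a nested list of
# class "databook" with distributions held as band x category matrices.

#' Assemble a databook
#'
#' Builds a `databook` object from its component blocks. Most users will not
#' call this directly: [read_databook()] builds one from a YAML file and
#' [generate_demo_databook()] builds the synthetic national fixture.
#'
#' @param region_name region label.
#' @param demographics list with `population_per_band` (named numeric over
#'   the five age bands), `annual_births` (named numeric per calendar year
#'   covering the horizon), `birth_outcome_fractions` (named numeric over
#'   the four birth outcomes, summing to one) and `poverty_fraction`.
#' @param mortality list with `u5mr` (deaths per 1000 live births),
#'   `neonatal_share` (fraction of under-5 deaths before one month), and
#'   cause-fraction vectors `cause_fractions_neonatal`,
#'   `cause_fractions_postneonatal`.
#' @param risks list with `stunting_distribution` and
#'   `breastfeeding_distribution` (5 x 4 matrices, rows = age bands) and
#'   `diarrhea_incidence` (episodes per child per month, named per band).
#' @param interventions named list (names from [intervention_names()]) of
#'   intervention specifications; see [intervention_spec()].
#' @param effects effect-size table; see [default_effect_sizes()].
#' @param horizon list with integer `start_year` and `end_year`.
#' @param validate if `TRUE`, stop when [validate_databook()] reports
#'   violations.
#' @return an object of class `databook`.
#' @export
databook <- function(region_name, demographics, mortality, risks,
                     interventions, effects, horizon, validate = TRUE) {
  db <- structure(
    list(region_name = region_name, horizon = horizon,
         demographics = demographics, mortality = mortality, risks = risks,
         interventions = interventions, effects = effects),
    class = "databook")
  if (validate) {
    v <- validate_databook(db)
    if (length(v) > 0) {
      stop("invalid databook:\n  ", paste(v, collapse = "\n  "),
           call. = FALSE)
    }
  }
  db
}

#' Specify one intervention program
#'
#' @param name program name, one of [intervention_names()]: antenatal
#'   micronutrient supplementation (AMS), balanced energy-protein
#'   supplementation (BEP), exclusive breastfeeding promotion (BFP), infant
#'   and young child feeding education (IYCF), public provision of
#'   complementary foods (CFS), vitamin A supplementation (VAS).
#' @param target_population list with `age_bands` (character, possibly
#'   empty), `poverty` (`"all"` or `"below"`) and `pregnant` (logical).
#' @param unit_cost USD per beneficiary per year; the marginal cost at low
#'   coverage.
#' @param baseline_coverage current coverage of the target group, in
#'   `[0, saturation]`.
#' @param saturation maximum attainable coverage, in `(0, 1]`.
#' @param target_pop_size optional explicit target-population denominator
#'   (e.g. campaign doses per year); when `NULL` the size is derived from
#'   the target-population rule and the databook demographics by
#'   [target_population_size()].
#' @return a list of class `intervention_spec`.
#' @export
intervention_spec <- function(name, target_population, unit_cost,
                              baseline_coverage, saturation = 0.95,
                              target_pop_size = NULL) {
  structure(
    list(name = name, target_population = target_population,
         unit_cost = unit_cost, baseline_coverage = baseline_coverage,
         saturation = saturation, target_pop_size = target_pop_size),
    class = "intervention_spec")
}

#' @export
print.databook <- function(x, ...) {
  cat("<databook> region:", x$region_name, "\n")
  cat("  horizon:", x$horizon$start_year, "-", x$horizon$end_year, "\n")
  cat("  under-5 population:",
      format(sum(x$demographics$population_per_band), big.mark = ","), "\n")
  cat("  U5MR:", x$mortality$u5mr, "per 1000; stunting prevalence:",
      sprintf("%.1f%%", 100 * aggregate_stunting_prevalence(x)), "\n")
  cat("  interventions:", paste(names(x$interventions), collapse = ", "),
      "\n")
  if (isTRUE(x$effects$placeholder)) {
    cat("  effect sizes: placeholder defaults\n")
  }
  invisible(x)
}

#' Population-weighted stunting prevalence implied by a databook
#'
#' @param db a databook.
#' @return the fraction of under-5 children in the moderate or severe
#'   height-for-age categories, weighted by band population.
#' @export
aggregate_stunting_prevalence <- function(db) {
  pop <- db$demographics$population_per_band
  sum(pop * stunted_fraction(db$risks$stunting_distribution)) / sum(pop)
}

# ---- validation -------------------------------------------------------------

check_dist <- function(v, nm, tol = 1e-9) {
  if (any(v < 0)) return(sprintf("%s: negative entries", nm))
  if (abs(sum(v) - 1) > tol) {
    return(sprintf("%s: sums to %.12g, expected 1", nm, sum(v)))
  }
  NULL
}

#' Validate a databook
#'
#' Checks every structural invariant of the databook: distributions sum to
#' one (tolerance 1e-9), counts and rates are non-negative, the births
#' series covers the horizon, coverages do not exceed saturations, and
#' effect sizes are positive with unit reference categories. Violations are
#' returned, not raised, so that a caller can report all of them at once.
#'
#' @param db a databook (any list with the databook blocks; class is not
#'   required so that partially-built books can be checked).
#' @return a character vector of violation messages; empty when valid.
#' @export
validate_databook <- function(db) {
  v <- character()
  bands <- age_bands()
  for (blk in c("region_name", "horizon", "demographics", "mortality",
                "risks", "interventions", "effects")) {
    if (is.null(db[[blk]])) v <- c(v, sprintf("missing block '%s'", blk))
  }
  if (length(v) > 0) return(v)

  dg <- db$demographics
  if (any(dg$population_per_band < 0)) {
    v <- c(v, "demographics: negative population_per_band")
  }
  if (!identical(sort(names(dg$population_per_band)), sort(bands))) {
    v <- c(v, "demographics: population_per_band must name all five age bands")
  }
  v <- c(v, check_dist(dg$birth_outcome_fractions,
                       "demographics: birth_outcome_fractions"))
  if (dg$poverty_fraction < 0 || dg$poverty_fraction > 1) {
    v <- c(v, "demographics: poverty_fraction outside [0,1]")
  }
  yrs <- as.integer(names(dg$annual_births))
  need <- seq(db$horizon$start_year, db$horizon$end_year)
  if (!all(need %in% yrs)) {
    v <- c(v, "demographics: annual_births does not cover the horizon")
  }
  if (any(dg$annual_births < 0)) {
    v <- c(v, "demographics: negative annual_births")
  }

  mo <- db$mortality
  if (!isTRUE(mo$u5mr > 0)) v <- c(v, "mortality: u5mr must be > 0")
  if (mo$neonatal_share < 0 || mo$neonatal_share > 1) {
    v <- c(v, "mortality: neonatal_share outside [0,1]")
  }
  v <- c(v, check_dist(mo$cause_fractions_neonatal,
                       "mortality: cause_fractions_neonatal"))
  v <- c(v, check_dist(mo$cause_fractions_postneonatal,
                       "mortality: cause_fractions_postneonatal"))

  rk <- db$risks
  for (b in bands) {
    v <- c(v, check_dist(rk$stunting_distribution[b, ],
                         sprintf("risks: stunting_distribution band %s", b)))
    v <- c(v, check_dist(rk$breastfeeding_distribution[b, ],
                         sprintf("risks: breastfeeding_distribution band %s",
                                 b)))
  }
  if (any(rk$diarrhea_incidence < 0)) {
    v <- c(v, "risks: negative diarrhea_incidence")
  }

  for (nm in names(db$interventions)) {
    iv <- db$interventions[[nm]]
    if (!iv$name %in% intervention_names()) {
      v <- c(v, sprintf("interventions: unknown program '%s'", iv$name))
    }
    if (!isTRUE(iv$unit_cost > 0)) {
      v <- c(v, sprintf("interventions: %s unit_cost must be > 0", nm))
    }
    if (iv$saturation <= 0 || iv$saturation > 1) {
      v <- c(v, sprintf("interventions: %s saturation outside (0,1]", nm))
    }
    if (iv$baseline_coverage < 0 ||
        iv$baseline_coverage > iv$saturation + 1e-12) {
      v <- c(v, sprintf(
        "interventions: %s baseline_coverage %.3g exceeds saturation %.3g",
        nm, iv$baseline_coverage, iv$saturation))
    }
  }

  v <- c(v, validate_effects(db$effects))
  v
}

validate_effects <- function(ef) {
  v <- character()
  pos <- function(x, nm) {
    if (any(unlist(x) <= 0)) sprintf("effects: %s must be > 0", nm) else NULL
  }
  v <- c(v, pos(ef$stunting_or_prev, "stunting_or_prev"))
  v <- c(v, pos(ef$stunting_or_birth, "stunting_or_birth"))
  v <- c(v, pos(ef$diarrhea_or_stunting, "diarrhea_or_stunting"))
  if (abs(ef$stunting_or_birth[["term_aga"]] - 1) > 1e-12) {
    v <- c(v, "effects: stunting_or_birth reference term_aga must be 1")
  }
  for (b in age_bands()) {
    rr <- ef$diarrhea_rr_bf[[b]]
    v <- c(v, pos(rr, sprintf("diarrhea_rr_bf band %s", b)))
    for (tab in names(ef$bf_mortality_rr[[b]])) {
      v <- c(v, pos(ef$bf_mortality_rr[[b]][[tab]],
                    sprintf("bf_mortality_rr band %s cause %s", b, tab)))
    }
  }
  for (cz in names(ef$stunting_mortality_rr)) {
    rr <- ef$stunting_mortality_rr[[cz]]
    v <- c(v, pos(rr, sprintf("stunting_mortality_rr cause %s", cz)))
    if (abs(rr[["normal"]] - 1) > 1e-12) {
      v <- c(v, sprintf(
        "effects: stunting_mortality_rr cause %s reference normal must be 1",
        cz))
    }
  }
  pe <- ef$program_effects
  for (nm in c("ams_birth_or", "bep_birth_or", "iycf_stunting_or",
               "iycf_mortality_rr", "cfs_stunting_or")) {
    v <- c(v, pos(pe[[nm]], nm))
  }
  for (nm in c("vas_diarrhea_incidence_reduction",
               "vas_diarrhea_mortality_reduction")) {
    if (pe[[nm]] < 0 || pe[[nm]] > 1) {
      v <- c(v, sprintf("effects: %s outside [0,1]", nm))
    }
  }
  v
}

# ---- YAML serialization -----------------------------------------------------

mat_to_yaml <- function(m) {
  out <- lapply(rownames(m), function(r) as.list(m[r, ]))
  names(out) <- rownames(m)
  out
}

yaml_to_mat <- function(lst, rows, cols, where) {
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  for (r in rows) {
    if (is.null(lst[[r]])) {
      stop(sprintf("databook load error in block '%s': missing band '%s'",
                   where, r), call. = FALSE)
    }
    for (cc in cols) {
      val <- lst[[r]][[cc]]
      if (is.null(val) || !is.numeric(val)) {
        stop(sprintf(
          "databook load error in block '%s': band '%s', category '%s'",
          where, r, cc), call. = FALSE)
      }
      m[r, cc] <- val
    }
  }
  m
}

databook_to_list <- function(db) {
  iv <- lapply(db$interventions, function(s) {
    out <- list(name = s$name,
                target_population = s$target_population,
                unit_cost = s$unit_cost,
                baseline_coverage = s$baseline_coverage,
                saturation = s$saturation)
    if (!is.null(s$target_pop_size)) out$target_pop_size <- s$target_pop_size
    out
  })
  list(
    region_name = db$region_name,
    horizon = list(start_year = db$horizon$start_year,
                   end_year = db$horizon$end_year),
    demographics = list(
      population_per_band = as.list(db$demographics$population_per_band),
      annual_births = as.list(db$demographics$annual_births),
      birth_outcome_fractions =
        as.list(db$demographics$birth_outcome_fractions),
      poverty_fraction = db$demographics$poverty_fraction),
    mortality = list(
      u5mr = db$mortality$u5mr,
      neonatal_share = db$mortality$neonatal_share,
      cause_fractions_neonatal = as.list(db$mortality$cause_fractions_neonatal),
      cause_fractions_postneonatal =
        as.list(db$mortality$cause_fractions_postneonatal)),
    risks = list(
      stunting_distribution = mat_to_yaml(db$risks$stunting_distribution),
      breastfeeding_distribution =
        mat_to_yaml(db$risks$breastfeeding_distribution),
      diarrhea_incidence = as.list(db$risks$diarrhea_incidence)),
    interventions = iv,
    effects = effects_to_list(db$effects))
}

effects_to_list <- function(ef) {
  list(
    placeholder = isTRUE(ef$placeholder),
    stunting_mortality_rr = lapply(ef$stunting_mortality_rr, as.list),
    bf_mortality_rr = lapply(ef$bf_mortality_rr,
                             function(bb) lapply(bb, as.list)),
    stunting_or_prev = ef$stunting_or_prev,
    stunting_or_birth = as.list(ef$stunting_or_birth),
    diarrhea_rr_bf = lapply(ef$diarrhea_rr_bf, as.list),
    diarrhea_or_stunting = ef$diarrhea_or_stunting,
    program_effects = ef$program_effects)
}

list_to_effects <- function(lst) {
  nv <- function(x) unlist(x)
  list(
    placeholder = isTRUE(lst$placeholder),
    stunting_mortality_rr = lapply(lst$stunting_mortality_rr, nv),
    bf_mortality_rr = lapply(lst$bf_mortality_rr,
                             function(bb) lapply(bb, nv)),
    stunting_or_prev = lst$stunting_or_prev,
    stunting_or_birth = nv(lst$stunting_or_birth),
    diarrhea_rr_bf = lapply(lst$diarrhea_rr_bf, nv),
    diarrhea_or_stunting = lst$diarrhea_or_stunting,
    program_effects = lst$program_effects)
}

#' Write a databook to a YAML file
#'
#' Serialization is canonical (fixed block order, 15 significant digits), so
#' writing, reading and writing again reproduces the file byte for byte.
#'
#' @param db a databook.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_databook <- function(db, path) {
  txt <- yaml::as.yaml(databook_to_list(db), precision = 15)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Read a databook from a YAML file
#'
#' @param path a YAML databook written by [write_databook()] (or authored by
#'   hand with the same block structure).
#' @param validate stop if the loaded book fails [validate_databook()].
#' @return a databook.
#' @export
read_databook <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    stop("databook load error: file not found: ", path, call. = FALSE)
  }
  lst <- yaml::read_yaml(path)
  for (blk in c("region_name", "horizon", "demographics", "mortality",
                "risks", "interventions", "effects")) {
    if (is.null(lst[[blk]])) {
      stop(sprintf("databook load error: missing block '%s' in %s",
                   blk, path), call. = FALSE)
    }
  }
  bands <- age_bands()
  dg <- lst$demographics
  demographics <- list(
    population_per_band = unlist(dg$population_per_band)[bands],
    annual_births = unlist(dg$annual_births),
    birth_outcome_fractions =
      unlist(dg$birth_outcome_fractions)[birth_outcomes()],
    poverty_fraction = dg$poverty_fraction)
  mo <- lst$mortality
  mortality <- list(
    u5mr = mo$u5mr,
    neonatal_share = mo$neonatal_share,
    cause_fractions_neonatal =
      unlist(mo$cause_fractions_neonatal)[causes_of_death("<1m")],
    cause_fractions_postneonatal =
      unlist(mo$cause_fractions_postneonatal)[causes_of_death("1-5m")])
  rk <- lst$risks
  risks <- list(
    stunting_distribution = yaml_to_mat(rk$stunting_distribution, bands,
                                        stunting_categories(),
                                        "risks/stunting_distribution"),
    breastfeeding_distribution =
      yaml_to_mat(rk$breastfeeding_distribution, bands,
                  breastfeeding_categories(),
                  "risks/breastfeeding_distribution"),
    diarrhea_incidence = unlist(rk$diarrhea_incidence)[bands])
  interventions <- lapply(lst$interventions, function(s) {
    tp <- s$target_population
    tp$age_bands <- as.character(unlist(tp$age_bands))
    intervention_spec(s$name, tp, s$unit_cost, s$baseline_coverage,
                      s$saturation, s$target_pop_size)
  })
  names(interventions) <- vapply(interventions, `[[`, "", "name")
  databook(lst$region_name, demographics, mortality, risks, interventions,
           list_to_effects(lst$effects),
           list(start_year = lst$horizon$start_year,
                end_year = lst$horizon$end_year),
           validate = validate)
}
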