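# Fixed category sets for the compartmental model. The engine indexes strata
# as a 16-vector per age band with stunting category varying fastest:
# idx(s, b) = s + 4 * (b - 1).

#' Age bands, risk categories and cause lists
#'
#' The model tracks children across five age bands (widths 1, 5, 6, 12 and 36
#' months), four height-for-age categories and four breastfeeding categories.
#' Children in the `moderate` and `severe` height-for-age categories (more
#' than two standard deviations below the reference norm) count as stunted.
#' Neonates can die of seven causes; older children of four.
#'
#' @return `age_bands()` returns the band names; `band_widths()` their widths
#'   in months; `stunting_categories()`, `breastfeeding_categories()`,
#'   `birth_outcomes()` the category label sets; `causes_of_death(band)` the
#'   cause list applicable to an age band.
#' @examples
#' age_bands()
#' causes_of_death("<1m")
#' @export
age_bands <- function() c("<1m", "1-5m", "6-11m", "12-23m", "24-59m")

#' @rdname age_bands
#' @export
band_widths <- function() {
  setNames(c(1L, 5L, 6L, 12L, 36L), age_bands())
}

#' @rdname age_bands
#' @export
stunting_categories <- function() c("normal", "mild", "moderate", "severe")

#' @rdname age_bands
#' @export
breastfeeding_categories <- function() {
  c("exclusive", "predominant", "partial", "none")
}

#' @rdname age_bands
#' @export
birth_outcomes <- function() {
  c("term_aga", "term_sga", "preterm_aga", "preterm_sga")
}

#' @param band an age band name.
#' @rdname age_bands
#' @export
causes_of_death <- function(band) {
  stopifnot(band %in% age_bands())
  if (band == "<1m") {
    c("diarrhea", "pneumonia", "meningitis", "asphyxia", "sepsis",
      "prematurity", "other")
  } else {
    c("diarrhea", "pneumonia", "measles", "other")
  }
}

# Union of the two cause lists, used for cumulative death tallies.
all_causes <- function() {
  c("diarrhea", "pneumonia", "meningitis", "asphyxia", "sepsis",
    "prematurity", "measles", "other")
}

#' @rdname age_bands
#' @export
intervention_names <- function() {
  c("AMS", "BEP", "BFP", "IYCF", "CFS", "VAS")
}

# logical mask over the 16 strata (stunting fastest) marking stunted strata
stunted_mask <- function() rep(c(FALSE, FALSE, TRUE, TRUE), 4L)

# stunted fraction of a per-band stunting distribution (length-4 vector or
# 5 x 4 matrix)
stunted_fraction <- function(dist) {
  if (is.matrix(dist)) {
    rowSums(dist[, c("moderate", "severe"), drop = FALSE])
  } else {
    sum(dist[c("moderate", "severe")])
  }
}
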