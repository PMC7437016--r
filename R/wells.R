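#' Wells score item weights
#'
#' The canonical seven-item Wells weighting for pulmonary embolism:
#' clinical signs of DVT (3), PE the most likely diagnosis (3), heart rate
#' above 100/min (1.5), recent immobilization or surgery (1.5), previous
#' VTE (1.5), hemoptysis (1), active cancer (1). All weights are
#' configurable but must be non-negative.
#'
#' @param dvt_signs,pe_most_likely,tachycardia,immobilization_or_surgery,history_vte,hemoptysis,cancer
#'   point values for the seven items.
#' @return an object of class `wells_weights`.
#' @export
wells_weights <- function(dvt_signs = 3, pe_most_likely = 3, tachycardia = 1.5,
                          immobilization_or_surgery = 1.5, history_vte = 1.5,
                          hemoptysis = 1, cancer = 1) {
  w <- list(
    dvt_signs = dvt_signs, pe_most_likely = pe_most_likely,
    tachycardia = tachycardia,
    immobilization_or_surgery = immobilization_or_surgery,
    history_vte = history_vte, hemoptysis = hemoptysis, cancer = cancer
  )
  if (any(vapply(w, function(x) !is.numeric(x) || length(x) != 1L || is.na(x) || x < 0,
                 logical(1)))) {
    stop2("all Wells weights must be single non-negative numbers")
  }
  structure(w, class = "wells_weights")
}

#' Clinical pretest probability (C-PTP) classification scheme
#'
#' Cut-points mapping a Wells score to the three-level (low / moderate /
#' high) and two-level (PE unlikely / PE likely) C-PTP categories. Two named
#' presets are provided:
#' \describe{
#'   \item{`"peged-trial"`}{low \eqn{\le} 4.0, moderate 4.5--6.0, high
#'     \eqn{\ge} 6.5 (on the half-point score lattice); the scheme used by
#'     the trial that defined the graduated D-dimer strategy. Default.}
#'   \item{`"traditional"`}{low < 2, moderate 2--6, high > 6.}
#' }
#' The two-level boundary is `pe_likely` iff score > `two_level_likely_min`
#' (strict), 4.0 under both presets.
#'
#' @param preset name of a preset, or `NULL` when supplying explicit bounds.
#' @param low_max inclusive upper bound of the low category.
#' @param moderate_max inclusive upper bound of the moderate category.
#' @param two_level_likely_min exclusive lower bound of "PE likely".
#' @return an object of class `cptp_scheme`.
#' @export
cptp_scheme <- function(preset = c("peged-trial", "traditional"),
                        low_max = NULL, moderate_max = NULL,
                        two_level_likely_min = 4) {
  if (is.null(low_max) || is.null(moderate_max)) {
    preset <- match.arg(preset)
    bounds <- switch(preset,
      "peged-trial" = c(low_max = 4, moderate_max = 6),
      "traditional" = c(low_max = 1.5, moderate_max = 6)
    )
    low_max <- low_max %||% bounds[["low_max"]]
    moderate_max <- moderate_max %||% bounds[["moderate_max"]]
    label <- preset
  } else {
    label <- "custom"
  }
  if (!(low_max > 0 && moderate_max > low_max)) {
    stop2("cptp_scheme requires 0 < low_max < moderate_max")
  }
  structure(
    list(low_max = low_max, moderate_max = moderate_max,
         two_level_likely_min = two_level_likely_min, preset = label),
    class = "cptp_scheme"
  )
}

#' Compute the Wells score
#'
#' Weighted sum over the seven Wells items. The tachycardia item fires when
#' `heart_rate > 100`; the immobilization-or-surgery item fires when either
#' `recent_immobilization` or `recent_surgery` is true. Vectorised over the
#' rows of `cohort`.
#'
#' @param cohort a `pe_cohort` (or any data frame with columns `dvt_signs`,
#'   `pe_most_likely`, `heart_rate`, `recent_immobilization`,
#'   `recent_surgery`, `history_vte`, `hemoptysis`, `active_cancer`).
#' @param weights a [wells_weights()] object.
#' @return numeric vector of scores, one per row, in
#'   `[0, sum(unlist(weights))]`.
#' @export
compute_wells_score <- function(cohort, weights = wells_weights()) {
  stopifnot(inherits(weights, "wells_weights"))
  weights$dvt_signs * cohort$dvt_signs +
    weights$pe_most_likely * cohort$pe_most_likely +
    weights$tachycardia * (cohort$heart_rate > 100) +
    weights$immobilization_or_surgery *
      (cohort$recent_immobilization | cohort$recent_surgery) +
    weights$history_vte * cohort$history_vte +
    weights$hemoptysis * cohort$hemoptysis +
    weights$cancer * cohort$active_cancer
}

#' Three-level C-PTP category
#'
#' `low` if score <= `low_max`, `moderate` if `low_max` < score <=
#' `moderate_max`, `high` otherwise. The three categories partition the
#' score range.
#'
#' @param score numeric Wells score(s), each >= 0.
#' @param scheme a [cptp_scheme()].
#' @return character vector in `c("low", "moderate", "high")`.
#' @export
cptp_three_level <- function(score, scheme = cptp_scheme()) {
  stopifnot(inherits(scheme, "cptp_scheme"))
  if (any(score < 0, na.rm = TRUE)) stop2("Wells score cannot be negative")
  ifelse(score <= scheme$low_max, "low",
         ifelse(score <= scheme$moderate_max, "moderate", "high"))
}

#' Two-level C-PTP category
#'
#' `pe_likely` iff score strictly exceeds `two_level_likely_min` (default
#' 4.0, so a score of exactly 4 is `pe_unlikely`).
#'
#' @inheritParams cptp_three_level
#' @return character vector in `c("pe_unlikely", "pe_likely")`.
#' @export
cptp_two_level <- function(score, scheme = cptp_scheme()) {
  stopifnot(inherits(scheme, "cptp_scheme"))
  if (any(score < 0, na.rm = TRUE)) stop2("Wells score cannot be negative")
  ifelse(score > scheme$two_level_likely_min, "pe_likely", "pe_unlikely")
}
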