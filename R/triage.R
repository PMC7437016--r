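#' Triage rule configuration
#'
#' All thresholds consumed by the five rule engines. Every D-dimer
#' comparison in every engine is strict ("less than"): a value exactly at a
#' cutoff goes to imaging.
#'
#' @param d_dimer_standard_cutoff ng/ml; the classic rule-out cutoff (500).
#' @param d_dimer_high_cutoff ng/ml; the relaxed cutoff used by the YEARS
#'   and PEGeD branches with no / low pretest signal (1000).
#' @param age_adjust_factor ng/ml per year of age for the age-adjusted
#'   cutoff (10).
#' @param age_adjust_min_age years; the age-adjusted cutoff applies strictly
#'   above this age ("older than 50"), i.e. from 51 up; at or below it the
#'   standard cutoff applies.
#' @param perc_age_max years; PERC requires age strictly below this (50).
#' @param perc_pulse_max beats/min; PERC requires pulse strictly below this (100).
#' @param perc_sao2_min percent; PERC requires SaO2 strictly above this (94).
#' @param wells a [wells_weights()] object.
#' @param scheme a [cptp_scheme()]; one shared scheme is applied across all
#'   engines in a run.
#' @param age_adjusted_requires_cptp_over_50 logical; whether the over-50
#'   branch of the age-adjusted rule also requires a low or moderate C-PTP
#'   (default `TRUE`, consistent with the rule's source trial).
#' @param perc_leg_swelling_from_dvt_signs logical; when `TRUE`, PERC's
#'   unilateral-leg-swelling criterion is derived from `dvt_signs` instead
#'   of the dedicated `unilateral_leg_swelling` field.
#' @return an object of class `triage_config`.
#' @export
triage_config <- function(d_dimer_standard_cutoff = 500,
                          d_dimer_high_cutoff = 1000,
                          age_adjust_factor = 10,
                          age_adjust_min_age = 50,
                          perc_age_max = 50,
                          perc_pulse_max = 100,
                          perc_sao2_min = 94,
                          wells = wells_weights(),
                          scheme = cptp_scheme(),
                          age_adjusted_requires_cptp_over_50 = TRUE,
                          perc_leg_swelling_from_dvt_signs = FALSE) {
  if (!(d_dimer_standard_cutoff > 0 && d_dimer_standard_cutoff <= d_dimer_high_cutoff)) {
    stop2("need 0 < d_dimer_standard_cutoff <= d_dimer_high_cutoff")
  }
  lims <- c(age_adjust_factor, age_adjust_min_age, perc_age_max,
            perc_pulse_max, perc_sao2_min)
  if (any(!is.finite(lims) | lims <= 0)) stop2("all triage limits must be positive")
  stopifnot(inherits(wells, "wells_weights"), inherits(scheme, "cptp_scheme"))
  structure(
    list(d_dimer_standard_cutoff = d_dimer_standard_cutoff,
         d_dimer_high_cutoff = d_dimer_high_cutoff,
         age_adjust_factor = age_adjust_factor,
         age_adjust_min_age = age_adjust_min_age,
         perc_age_max = perc_age_max,
         perc_pulse_max = perc_pulse_max,
         perc_sao2_min = perc_sao2_min,
         wells = wells, scheme = scheme,
         age_adjusted_requires_cptp_over_50 = age_adjusted_requires_cptp_over_50,
         perc_leg_swelling_from_dvt_signs = perc_leg_swelling_from_dvt_signs),
    class = "triage_config"
  )
}

#' @rdname triage_cohort
#' @export
pe_algorithms <- function() c("standard", "age_adjusted", "years", "perc", "peged")

decision_tbl <- function(algorithm, cohort, rule_out, fired_clause,
                         cptp_category, threshold_applied) {
  tibble(
    patient_id = as.character(cohort$patient_id),
    algorithm = algorithm,
    verdict = ifelse(rule_out, "rule_out", "imaging_required"),
    fired_clause = fired_clause,
    cptp_category = cptp_category,
    d_dimer = cohort$d_dimer,
    threshold_applied = threshold_applied
  )
}

# "a; b; c" listing of failed criteria, built column-wise
failed_list <- function(fails) {
  apply(fails, 1L, function(row) paste(names(row)[row], collapse = "; "))
}

#' Standard algorithm
#'
#' PE is ruled out by a low C-PTP together with a D-dimer below the standard
#' cutoff (500 ng/ml); every other patient requires chest imaging.
#'
#' @param cohort a validated `pe_cohort`.
#' @param config a [triage_config()].
#' @return a decision tibble with columns `patient_id`, `algorithm`,
#'   `verdict` (`"rule_out"` / `"imaging_required"`), `fired_clause`,
#'   `cptp_category`, `d_dimer`, `threshold_applied`.
#' @export
standard_algorithm <- function(cohort, config = triage_config()) {
  cptp <- cptp_three_level(compute_wells_score(cohort, config$wells), config$scheme)
  cut <- config$d_dimer_standard_cutoff
  low <- cptp == "low"
  dd_ok <- cohort$d_dimer < cut
  fails <- cbind(`C-PTP not low` = !low,
                 `D-dimer at/above standard cutoff` = !dd_ok)
  clause <- ifelse(low & dd_ok,
                   sprintf("low C-PTP and D-dimer < %g ng/ml", cut),
                   failed_list(fails))
  decision_tbl("standard", cohort, low & dd_ok, clause, cptp,
               rep(cut, nrow(cohort)))
}

#' Age-adjusted D-dimer algorithm
#'
#' At or below 50 years the standard cutoff applies; strictly above 50 the
#' cutoff is `age_adjust_factor` times the age in years (10 x age). PE is
#' ruled out when the C-PTP is low or moderate and the D-dimer is below the
#' effective cutoff. The C-PTP requirement on the over-50 branch can be
#' lifted via `age_adjusted_requires_cptp_over_50 = FALSE`.
#'
#' @inheritParams standard_algorithm
#' @inherit standard_algorithm return
#' @export
age_adjusted_algorithm <- function(cohort, config = triage_config()) {
  cptp <- cptp_three_level(compute_wells_score(cohort, config$wells), config$scheme)
  over50 <- cohort$age > config$age_adjust_min_age
  cutoff <- ifelse(over50, cohort$age * config$age_adjust_factor,
                   config$d_dimer_standard_cutoff)
  cptp_ok <- cptp %in% c("low", "moderate")
  if (!config$age_adjusted_requires_cptp_over_50) cptp_ok <- cptp_ok | over50
  dd_ok <- cohort$d_dimer < cutoff
  fails <- cbind(`C-PTP high` = !cptp_ok,
                 `D-dimer at/above age-adjusted cutoff` = !dd_ok)
  clause <- ifelse(cptp_ok & dd_ok,
                   sprintf("low/moderate C-PTP and D-dimer < %g ng/ml", cutoff),
                   failed_list(fails))
  decision_tbl("age_adjusted", cohort, cptp_ok & dd_ok, clause, cptp, cutoff)
}

#' YEARS algorithm
#'
#' Counts the three YEARS items (clinical signs of DVT, hemoptysis, PE the
#' most likely diagnosis). With zero items PE is ruled out below the high
#' cutoff (1000 ng/ml); with one or more items, below the standard cutoff
#' (500 ng/ml). The Wells C-PTP is not consulted.
#'
#' @inheritParams standard_algorithm
#' @inherit standard_algorithm return
#' @export
years_algorithm <- function(cohort, config = triage_config()) {
  items <- cohort$dvt_signs + cohort$hemoptysis + cohort$pe_most_likely
  cutoff <- ifelse(items == 0, config$d_dimer_high_cutoff,
                   config$d_dimer_standard_cutoff)
  dd_ok <- cohort$d_dimer < cutoff
  clause <- ifelse(dd_ok,
                   sprintf("%d YEARS item(s) and D-dimer < %g ng/ml", items, cutoff),
                   sprintf("%d YEARS item(s) and D-dimer >= %g ng/ml", items, cutoff))
  decision_tbl("years", cohort, dd_ok, clause, NA_character_, cutoff)
}

#' PERC rule
#'
#' PE is ruled out only when all eight criteria hold: age < 50 years,
#' SaO2 > 94%, pulse < 100/min, no hemoptysis, no recent trauma or surgery,
#' no history of VTE, no unilateral leg swelling, no oral hormone use. All
#' comparisons are strict. No D-dimer is consulted. When any criterion
#' fails, `fired_clause` lists every failed criterion.
#'
#' @inheritParams standard_algorithm
#' @inherit standard_algorithm return
#' @export
perc_algorithm <- function(cohort, config = triage_config()) {
  swelling <- if (config$perc_leg_swelling_from_dvt_signs) cohort$dvt_signs
              else cohort$unilateral_leg_swelling
  fails <- cbind(
    `age >= 50` = !(cohort$age < config$perc_age_max),
    `SaO2 <= 94%` = !(cohort$sao2 > config$perc_sao2_min),
    `pulse >= 100/min` = !(cohort$heart_rate < config$perc_pulse_max),
    `hemoptysis` = cohort$hemoptysis,
    `recent trauma or surgery` = cohort$recent_trauma | cohort$recent_surgery,
    `history of VTE` = cohort$history_vte,
    `unilateral leg swelling` = swelling,
    `oral hormone use` = cohort$oral_hormone_use
  )
  ok <- rowSums(fails) == 0
  clause <- ifelse(ok, "all PERC criteria negative", failed_list(fails))
  decision_tbl("perc", cohort, ok, clause, NA_character_,
               rep(NA_real_, nrow(cohort)))
}

#' PEGeD (graduated D-dimer) algorithm
#'
#' C-PTP-stratified D-dimer thresholds: PE is ruled out with a low C-PTP
#' and D-dimer below the high cutoff (1000 ng/ml), or with a moderate C-PTP
#' and D-dimer below the standard cutoff (500 ng/ml). A high C-PTP always
#' goes to imaging.
#'
#' @inheritParams standard_algorithm
#' @inherit standard_algorithm return
#' @export
peged_algorithm <- function(cohort, config = triage_config()) {
  cptp <- cptp_three_level(compute_wells_score(cohort, config$wells), config$scheme)
  cutoff <- ifelse(cptp == "low", config$d_dimer_high_cutoff,
                   ifelse(cptp == "moderate", config$d_dimer_standard_cutoff, NA_real_))
  ok <- !is.na(cutoff) & cohort$d_dimer < cutoff
  clause <- ifelse(ok, sprintf("%s C-PTP and D-dimer < %g ng/ml", cptp, cutoff),
                   ifelse(cptp == "high", "high C-PTP",
                          sprintf("%s C-PTP and D-dimer >= %g ng/ml", cptp, cutoff)))
  decision_tbl("peged", cohort, ok, clause, cptp, cutoff)
}

#' Run triage algorithms over a cohort
#'
#' Applies the requested rule engines to every patient and stacks the
#' per-algorithm decision tables. Decisions are deterministic functions of
#' the record and configuration; the reference-standard column is never
#' consulted.
#'
#' @inheritParams standard_algorithm
#' @param algorithms character vector of engine names; see [pe_algorithms()].
#' @return a decision tibble with one row per (patient, algorithm).
#' @export
triage_cohort <- function(cohort, config = triage_config(),
                          algorithms = pe_algorithms()) {
  unknown <- setdiff(algorithms, pe_algorithms())
  if (length(unknown)) {
    stop2("unknown algorithm(s): ", paste(unknown, collapse = ", "),
          "; valid names are: ", paste(pe_algorithms(), collapse = ", "))
  }
  engines <- list(standard = standard_algorithm,
                  age_adjusted = age_adjusted_algorithm,
                  years = years_algorithm,
                  perc = perc_algorithm,
                  peged = peged_algorithm)
  out <- lapply(algorithms, function(a) engines[[a]](cohort, config))
  if (!length(out)) return(decision_tbl(character(0), cohort[0, ], logical(0),
                                        character(0), character(0), numeric(0)))
  do.call(rbind, out)
}
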