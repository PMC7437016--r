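# build a cohort tibble with sensible defaults, overriding any column;
# vectors are recycled to n rows
make_cohort <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = 60, heart_rate = 80, sao2 = 96, d_dimer = 400,
    dvt_signs = FALSE, pe_most_likely = FALSE, hemoptysis = FALSE,
    recent_immobilization = FALSE, recent_surgery = FALSE,
    recent_trauma = FALSE, history_vte = FALSE, active_cancer = FALSE,
    oral_hormone_use = FALSE, unilateral_leg_swelling = FALSE,
    bode_index = NA_real_, confirmed_pe = NA
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# random records spanning the rule-relevant ranges
random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  rb <- function() sample(c(TRUE, FALSE), n, replace = TRUE)
  make_cohort(
    n,
    age = sample(18:95, n, replace = TRUE),
    heart_rate = sample(55:140, n, replace = TRUE),
    sao2 = round(runif(n, 85, 100), 1),
    d_dimer = round(runif(n, 0, 2500), 1),
    dvt_signs = rb(), pe_most_likely = rb(), hemoptysis = rb(),
    recent_immobilization = rb(), recent_surgery = rb(), recent_trauma = rb(),
    history_vte = rb(), active_cancer = rb(), oral_hormone_use = rb(),
    unilateral_leg_swelling = rb(),
    confirmed_pe = rb()
  )
}

verdict_of <- function(decisions) {
  stats::setNames(decisions$verdict, decisions$patient_id)
}
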