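# clause-by-clause re-statements of the five rules, written against the
# clinical definitions and independent of the engine code
oracle_cptp <- function(co) {
  s <- 3 * co$dvt_signs + 3 * co$pe_most_likely + 1.5 * (co$heart_rate > 100) +
    1.5 * (co$recent_immobilization | co$recent_surgery) +
    1.5 * co$history_vte + co$hemoptysis + co$active_cancer
  ifelse(s <= 4, "low", ifelse(s <= 6, "moderate", "high"))
}
oracle_standard <- function(co) oracle_cptp(co) == "low" & co$d_dimer < 500
oracle_age_adjusted <- function(co) {
  cut <- ifelse(co$age > 50, 10 * co$age, 500)
  oracle_cptp(co) %in% c("low", "moderate") & co$d_dimer < cut
}
oracle_years <- function(co) {
  k <- co$dvt_signs + co$hemoptysis + co$pe_most_likely
  (k == 0 & co$d_dimer < 1000) | (k >= 1 & co$d_dimer < 500)
}
oracle_perc <- function(co) {
  co$age < 50 & co$sao2 > 94 & co$heart_rate < 100 & !co$hemoptysis &
    !(co$recent_trauma | co$recent_surgery) & !co$history_vte &
    !co$unilateral_leg_swelling & !co$oral_hormone_use
}
oracle_peged <- function(co) {
  cptp <- oracle_cptp(co)
  (cptp == "low" & co$d_dimer < 1000) | (cptp == "moderate" & co$d_dimer < 500)
}

rule_out <- function(dec) dec$verdict == "rule_out"

test_that("all five engines agree with brute-force clause re-statements on an exhaustive grid", {
  bools <- rep(list(c(FALSE, TRUE)), 10)
  names(bools) <- c("dvt_signs", "pe_most_likely", "hemoptysis",
                    "recent_immobilization", "recent_surgery", "recent_trauma",
                    "history_vte", "active_cancer", "oral_hormone_use",
                    "unilateral_leg_swelling")
  grid <- expand.grid(c(bools, list(
    age = c(30, 49, 50, 51, 80),
    d_dimer = c(0, 499, 500, 799, 800, 999, 1000, 1500),
    heart_rate = c(80, 100, 120),
    sao2 = c(90, 94, 95)
  )))
  grid$patient_id <- sprintf("G%06d", seq_len(nrow(grid)))
  grid$bode_index <- NA_real_
  grid$confirmed_pe <- NA
  expect_gte(nrow(grid), 2^7 * 5 * 8 * 3 * 3)

  expect_equal(rule_out(standard_algorithm(grid)), oracle_standard(grid))
  expect_equal(rule_out(age_adjusted_algorithm(grid)), oracle_age_adjusted(grid))
  expect_equal(rule_out(years_algorithm(grid)), oracle_years(grid))
  expect_equal(rule_out(perc_algorithm(grid)), oracle_perc(grid))
  expect_equal(rule_out(peged_algorithm(grid)), oracle_peged(grid))
})

test_that("standard rule: strict 500 ng/ml boundary, low C-PTP required", {
  low <- make_cohort(2, d_dimer = c(499, 500))
  v <- verdict_of(standard_algorithm(low))
  expect_equal(unname(v), c("rule_out", "imaging_required"))
  high <- make_cohort(1, dvt_signs = TRUE, pe_most_likely = TRUE,
                      heart_rate = 120, d_dimer = 100)
  expect_equal(standard_algorithm(high)$verdict, "imaging_required")
})

test_that("age-adjusted rule: cutoff 10 x age strictly above 50, standard at or below", {
  moderate80 <- make_cohort(2, age = 80, dvt_signs = TRUE,
                            recent_immobilization = TRUE, d_dimer = c(750, 800))
  dec <- age_adjusted_algorithm(moderate80)
  expect_equal(dec$verdict, c("rule_out", "imaging_required"))
  expect_equal(dec$threshold_applied, c(800, 800))
  # at 50 or younger the 500 cutoff applies even with a low C-PTP
  expect_equal(age_adjusted_algorithm(make_cohort(1, age = 45, d_dimer = 600))$verdict,
               "imaging_required")
  expect_equal(age_adjusted_algorithm(make_cohort(1, age = 50, d_dimer = 499))$verdict,
               "rule_out")
  # dropping the C-PTP requirement on the over-50 branch is configurable
  high80 <- make_cohort(1, age = 80, dvt_signs = TRUE, pe_most_likely = TRUE,
                        heart_rate = 120, d_dimer = 700)
  expect_equal(age_adjusted_algorithm(high80)$verdict, "imaging_required")
  cfg <- triage_config(age_adjusted_requires_cptp_over_50 = FALSE)
  expect_equal(age_adjusted_algorithm(high80, cfg)$verdict, "rule_out")
})

test_that("YEARS rule: graduated cutoff on the three-item count", {
  expect_equal(years_algorithm(make_cohort(1, d_dimer = 999))$verdict, "rule_out")
  expect_equal(years_algorithm(make_cohort(1, d_dimer = 1000))$verdict,
               "imaging_required")
  expect_equal(years_algorithm(make_cohort(1, hemoptysis = TRUE, d_dimer = 600))$verdict,
               "imaging_required")
  expect_equal(years_algorithm(make_cohort(1, hemoptysis = TRUE, d_dimer = 499))$verdict,
               "rule_out")
})

test_that("PERC rule: all eight criteria strict; failures are listed", {
  ok <- make_cohort(1, age = 45, sao2 = 96, heart_rate = 80)
  expect_equal(perc_algorithm(ok)$verdict, "rule_out")
  # SaO2 boundary is strict (> 94)
  expect_equal(perc_algorithm(make_cohort(1, age = 49, sao2 = 94))$verdict,
               "imaging_required")
  old <- perc_algorithm(make_cohort(1, age = 67, sao2 = 96))
  expect_equal(old$verdict, "imaging_required")
  expect_match(old$fired_clause, "age")
  multi <- perc_algorithm(make_cohort(1, age = 67, sao2 = 90, history_vte = TRUE))
  expect_match(multi$fired_clause, "age >= 50")
  expect_match(multi$fired_clause, "SaO2")
  expect_match(multi$fired_clause, "VTE")
  # leg swelling can be derived from DVT signs by configuration
  dvt <- make_cohort(1, age = 45, sao2 = 96, dvt_signs = TRUE)
  expect_equal(perc_algorithm(dvt)$verdict, "rule_out")
  cfg <- triage_config(perc_leg_swelling_from_dvt_signs = TRUE)
  expect_equal(perc_algorithm(dvt, cfg)$verdict, "imaging_required")
})

test_that("PEGeD rule: C-PTP-stratified cutoffs; high C-PTP always imaged", {
  expect_equal(peged_algorithm(make_cohort(1, d_dimer = 999))$verdict, "rule_out")
  mod <- make_cohort(2, dvt_signs = TRUE, recent_immobilization = TRUE,
                     d_dimer = c(499, 500))
  expect_equal(peged_algorithm(mod)$verdict, c("rule_out", "imaging_required"))
  high <- make_cohort(1, dvt_signs = TRUE, pe_most_likely = TRUE,
                      heart_rate = 120, d_dimer = 200)
  expect_equal(peged_algorithm(high)$verdict, "imaging_required")
})

test_that("triage_cohort stacks one decision per patient and algorithm", {
  co <- make_cohort(1, d_dimer = 700)
  all5 <- triage_cohort(co)
  expect_equal(nrow(all5), 5)
  expect_setequal(all5$algorithm, pe_algorithms())
  # low C-PTP with D-dimer 700: imaged by the standard rule, ruled out by PEGeD
  expect_equal(all5$verdict[all5$algorithm == "standard"], "imaging_required")
  expect_equal(all5$verdict[all5$algorithm == "peged"], "rule_out")
  expect_equal(nrow(triage_cohort(co, algorithms = character(0))), 0)
  expect_error(triage_cohort(co, algorithms = c("peged", "geneva")),
               "geneva.*standard")
})

test_that("decisions are deterministic and never consult the reference standard", {
  co <- random_cohort(500, seed = 11)
  co2 <- co
  co2$confirmed_pe <- !co$confirmed_pe
  d1 <- triage_cohort(co)
  expect_identical(d1, triage_cohort(co))
  expect_identical(d1, triage_cohort(co2))
})

test_that("rule-out sets nest: PEGeD and age-adjusted extend the standard rule", {
  co <- random_cohort(10000, seed = 5)
  std <- rule_out(standard_algorithm(co))
  expect_true(all(std <= rule_out(peged_algorithm(co))))
  expect_true(all(std <= rule_out(age_adjusted_algorithm(co))))
})

test_that("raising D-dimer never converts an imaging verdict into a rule-out", {
  co <- random_cohort(10000, seed = 9)
  engines <- list(standard_algorithm, age_adjusted_algorithm, years_algorithm,
                  perc_algorithm, peged_algorithm)
  raised <- co
  raised$d_dimer <- co$d_dimer * 2 + 100
  for (engine in engines) {
    expect_true(all(rule_out(engine(raised)) <= rule_out(engine(co))))
  }
})
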