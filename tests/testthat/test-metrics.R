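test_that("confusion matrix tallies decisions against the reference standard", {
  co <- make_cohort(4, confirmed_pe = c(TRUE, FALSE, TRUE, FALSE),
                    d_dimer = c(2000, 2000, 100, 100))
  dec <- standard_algorithm(co)  # first two imaged, last two ruled out
  cm <- build_confusion_matrix(dec, co)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(1, 1, 1, 1))
  expect_equal(cm$n, 4)

  all_img <- make_cohort(10, d_dimer = 5000,
                         confirmed_pe = rep(c(TRUE, FALSE), 5))
  cm <- build_confusion_matrix(standard_algorithm(all_img), all_img)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(5, 5, 0, 0))

  all_ro <- make_cohort(3, d_dimer = 100, confirmed_pe = TRUE)
  cm <- build_confusion_matrix(standard_algorithm(all_ro), all_ro)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(0, 0, 3, 0))
})

test_that("confusion matrix matches a brute-force count on random decisions", {
  co <- random_cohort(400, seed = 21)
  for (alg in c("years", "perc", "peged")) {
    dec <- triage_cohort(co, algorithms = alg)
    cm <- build_confusion_matrix(dec, co)
    pos <- dec$verdict == "imaging_required"
    truth <- co$confirmed_pe[match(dec$patient_id, co$patient_id)]
    expect_equal(cm$tp, sum(pos & truth))
    expect_equal(cm$fp, sum(pos & !truth))
    expect_equal(cm$fn, sum(!pos & truth))
    expect_equal(cm$tn, sum(!pos & !truth))
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, nrow(co))
  }
})

test_that("duplicate or orphan decisions are rejected", {
  co <- make_cohort(2, confirmed_pe = c(TRUE, FALSE))
  dec <- standard_algorithm(co)
  expect_error(build_confusion_matrix(rbind(dec, dec[1, ]), co), "duplicate")
  bad <- dec
  bad$patient_id[2] <- "GHOST"
  expect_error(build_confusion_matrix(bad, co), "GHOST")
})

test_that("perfect and degenerate classifiers are handled without error", {
  m <- compute_metrics(pe_confusion(10, 0, 0, 10))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$youden, 1)
  expect_equal(m$nlr, 0)
  expect_true(is.na(m$plr))  # 1 - specificity = 0
  # unobservable fn/tn propagate as N/A, ppv stays computable
  m <- compute_metrics(pe_confusion(210, 948, NA, NA))
  expect_true(is.na(m$sensitivity) && is.na(m$npv) && is.na(m$accuracy))
  expect_equal(m$ppv, 18.1)
  expect_equal(m$imaging_count, 1158)
})

test_that("exact convention satisfies the Bayes identity and metric chain", {
  set.seed(14)
  for (i in 1:20) {
    cts <- rmultinom(1, 500, runif(4, 0.05, 1))
    m <- compute_metrics(pe_confusion(cts[1], cts[2], cts[3], cts[4]),
                         rounding = "exact")
    prev <- (m$tp + m$fn) / m$n
    ppv <- m$ppv / 100
    expect_equal(ppv / (1 - ppv), m$plr * prev / (1 - prev), tolerance = 1e-9)
    expect_equal(m$youden, m$sensitivity / 100 + m$specificity / 100 - 1,
                 tolerance = 1e-12)
    expect_equal(m$accuracy / 100, (m$tp + m$tn) / m$n, tolerance = 1e-12)
    expect_equal(m$imaging_count + (m$fn + m$tn), m$n)
  }
})

test_that("pairwise differences: identity is zero and N/A missed flags propagate", {
  a <- compute_metrics(pe_confusion(186, 183, 24, 765, algorithm = "peged"))
  s <- compute_metrics(pe_confusion(210, 948, NA, NA, algorithm = "standard"))
  self <- pairwise_difference(a, a, 1158)
  expect_equal(unlist(self[, c("imaging_diff", "imaging_diff_pct",
                               "missed_diff", "missed_diff_pct")]),
               c(imaging_diff = 0, imaging_diff_pct = 0,
                 missed_diff = 0, missed_diff_pct = 0))
  vs_std <- pairwise_difference(a, s, 1158)
  expect_true(vs_std$not_applicable_missed)
  expect_equal(vs_std$imaging_diff, -789)
  expect_error(pairwise_difference(a, s, 0), "positive")
})

test_that("summary-statistic t-test agrees with t.test on raw data", {
  set.seed(8)
  x <- rnorm(40, 10, 2); y <- rnorm(25, 12, 3)
  ours <- ttest_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 25)
  ref <- t.test(x, y)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  ours_p <- ttest_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 25,
                               var_equal = TRUE)
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours_p$p_value, ref_p$p.value, tolerance = 1e-12)
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 30), "at least 2")
})

test_that("group comparison table covers the cohort characteristics", {
  co <- generate_cohort(cohort_sim_config(n_total = 400, seed = 33))
  tab <- compare_groups(co)
  expect_true(all(c("d_dimer", "wells_score", "dvt_signs", "hr_gt_100",
                    "sao2_le_94", "pe_likely", "age_lt_50") %in% tab$variable))
  expect_true(all(tab$p_value[tab$computable] >= 0 &
                    tab$p_value[tab$computable] <= 1))
  # cross-check one binary row against a direct chi-square
  g <- co$confirmed_pe
  ref <- chisq.test(table(co$dvt_signs, g), correct = FALSE)$p.value
  expect_equal(tab$p_value[tab$variable == "dvt_signs"], ref, tolerance = 1e-12)
  # and one continuous row against a direct Welch test
  ref_t <- t.test(co$d_dimer[!g], co$d_dimer[g])$p.value
  expect_equal(tab$p_value[tab$variable == "d_dimer"], ref_t, tolerance = 1e-12)
})

test_that("chi-square on identical proportions gives p = 1", {
  expect_equal(chisq_from_counts(50, 100, 25, 50)$p.value, 1)
})

test_that("reports are deterministic and the format is validated", {
  metrics <- evaluate_decisions(
    triage_cohort(random_cohort(200, seed = 2)), random_cohort(200, seed = 2))
  cmp <- pairwise_table(metrics, 200)
  for (fmt in c("markdown", "tsv", "json")) {
    r1 <- render_report(metrics, cmp, format = fmt)
    r2 <- render_report(metrics, cmp, format = fmt)
    expect_identical(r1, r2)
  }
  md <- render_report(metrics, cmp, format = "markdown")
  expect_match(md, "peged-trial")
  expect_match(md, "rounding convention: paper")
  expect_no_error(render_report(metrics["peged"], NULL, format = "json"))
  expect_error(render_report(metrics, cmp, format = "xml"))
  expect_error(render_report(list(), NULL), "at least one")
})
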