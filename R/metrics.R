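#' 2x2 confusion matrix for a triage algorithm
#'
#' A positive prediction is `imaging_required` (PE not excluded), so a
#' false negative is a missed diagnosis: a patient with confirmed PE whom
#' the rule ruled out without imaging. `fn` and `tn` may be `NA` when a
#' study design makes them unobservable (e.g. when the rule under
#' evaluation defined the imaging set); metrics needing them are then
#' reported as not applicable.
#'
#' @param tp,fp,fn,tn non-negative integer counts (`fn`, `tn` may be `NA`).
#' @param algorithm optional algorithm label carried through to reports.
#' @return an object of class `pe_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`, `n` (`tp+fp+fn+tn`, counting `NA` cells as absent).
#' @export
pe_confusion <- function(tp, fp, fn = NA_integer_, tn = NA_integer_,
                         algorithm = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  obs <- counts[!is.na(counts)]
  if (any(obs < 0) || any(obs != round(obs))) {
    stop2("confusion-matrix counts must be non-negative integers")
  }
  if (any(is.na(c(tp, fp)))) stop2("tp and fp must be observed counts")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = sum(obs),
                 algorithm = algorithm),
            class = "pe_confusion")
}

#' Tally decisions against the reference standard
#'
#' Cross-tabulates one algorithm's verdicts with each patient's
#' `confirmed_pe` label. Every patient must carry a truth label and have
#' exactly one decision.
#'
#' @param decisions a decision tibble for a single algorithm (as returned
#'   by e.g. [peged_algorithm()]).
#' @param cohort the `pe_cohort` the decisions were made on, with
#'   `confirmed_pe` present for every patient.
#' @return a [pe_confusion()] object.
#' @export
build_confusion_matrix <- function(decisions, cohort) {
  require_truth(cohort)
  if (length(unique(decisions$algorithm)) > 1L) {
    stop2("decisions for a single algorithm expected; got: ",
          paste(unique(decisions$algorithm), collapse = ", "))
  }
  dup <- duplicated(decisions$patient_id)
  if (any(dup)) {
    stop2("duplicate decision(s) for patient(s): ",
          paste(unique(decisions$patient_id[dup]), collapse = ", "))
  }
  idx <- match(decisions$patient_id, cohort$patient_id)
  if (anyNA(idx)) {
    stop2("decision(s) for unknown patient(s): ",
          paste(decisions$patient_id[is.na(idx)], collapse = ", "))
  }
  truth <- cohort$confirmed_pe[idx]
  positive <- decisions$verdict == "imaging_required"
  pe_confusion(
    tp = sum(positive & truth), fp = sum(positive & !truth),
    fn = sum(!positive & truth), tn = sum(!positive & !truth),
    algorithm = unique(decisions$algorithm) %||% NA_character_
  )
}

ratio_or_na <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
}

#' Diagnostic accuracy panel from a confusion matrix
#'
#' Computes sensitivity, specificity, PPV, NPV, positive and negative
#' likelihood ratios, Youden index and diagnostic accuracy, plus the
#' imaging burden (`tp+fp`) and missed-diagnosis count (`fn`).
#'
#' Two reporting conventions are supported. Under `"paper"` (default, the
#' convention of the clinical literature this package reproduces),
#' percentages are rounded half-up to one decimal, and the likelihood
#' ratios and Youden index are computed from sensitivity and specificity
#' first rounded to three-decimal proportions, then themselves rounded to
#' three decimals. Under `"exact"` nothing is rounded. Metrics with a zero
#' (or unobservable) denominator are reported as `NA` (rendered "N/A"),
#' never thrown.
#'
#' @param cm a [pe_confusion()] object.
#' @param rounding `"paper"` or `"exact"`.
#' @return an object of class `dta_metrics`: a list with the eight metrics
#'   (percent scale for sensitivity, specificity, ppv, npv, accuracy),
#'   `imaging_count`, `missed_count`, the input counts and the convention.
#' @export
compute_metrics <- function(cm, rounding = c("paper", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(cm, "pe_confusion"))
  s <- ratio_or_na(cm$tp, cm$tp + cm$fn)
  c_ <- ratio_or_na(cm$tn, cm$tn + cm$fp)
  ppv <- ratio_or_na(cm$tp, cm$tp + cm$fp)
  npv <- ratio_or_na(cm$tn, cm$tn + cm$fn)
  acc <- if (is.na(cm$fn) || is.na(cm$tn)) NA_real_ else (cm$tp + cm$tn) / cm$n

  if (rounding == "paper") {
    s3 <- round_half_up(s, 3); c3 <- round_half_up(c_, 3)
    plr <- round_half_up(ratio_or_na(s3, 1 - c3), 3)
    nlr <- round_half_up(ratio_or_na(1 - s3, c3), 3)
    youden <- if (is.na(s3) || is.na(c3)) NA_real_ else round_half_up(s3 + c3 - 1, 3)
    pct <- function(x) round_half_up(100 * x, 1)
  } else {
    plr <- ratio_or_na(s, 1 - c_)
    nlr <- ratio_or_na(1 - s, c_)
    youden <- if (is.na(s) || is.na(c_)) NA_real_ else s + c_ - 1
    pct <- function(x) 100 * x
  }

  structure(
    list(algorithm = cm$algorithm,
         tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, n = cm$n,
         sensitivity = pct(s), specificity = pct(c_),
         ppv = pct(ppv), npv = pct(npv),
         plr = plr, nlr = nlr, youden = youden, accuracy = pct(acc),
         imaging_count = cm$tp + cm$fp,
         missed_count = cm$fn,
         rounding = rounding),
    class = "dta_metrics"
  )
}

#' @export
print.dta_metrics <- function(x, ...) {
  fmt <- function(v, d = 1) ifelse(is.na(v), "N/A", formatC(v, format = "f", digits = d))
  cat(sprintf("Diagnostic accuracy panel%s (%s rounding)\n",
              if (is.na(x$algorithm)) "" else paste0(" - ", x$algorithm), x$rounding))
  cat(sprintf("  TP %s  FP %s  FN %s  TN %s  (n = %d)\n",
              x$tp, x$fp, ifelse(is.na(x$fn), "N/A", x$fn),
              ifelse(is.na(x$tn), "N/A", x$tn), x$n))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  cat(sprintf("  PLR %s  NLR %s  Youden %s  accuracy %s%%\n",
              fmt(x$plr, 3), fmt(x$nlr, 3), fmt(x$youden, 3), fmt(x$accuracy)))
  cat(sprintf("  imaging %d  missed %s\n", x$imaging_count,
              ifelse(is.na(x$missed_count), "N/A", x$missed_count)))
  invisible(x)
}

#' Evaluate a decision table against the reference standard
#'
#' Splits a multi-algorithm decision table, tallies each algorithm's
#' confusion matrix and computes its metric panel.
#'
#' @param decisions a decision tibble from [triage_cohort()].
#' @inheritParams build_confusion_matrix
#' @inheritParams compute_metrics
#' @return a named list of `dta_metrics`, one per algorithm, in the order
#'   the algorithms first appear in `decisions`.
#' @export
evaluate_decisions <- function(decisions, cohort, rounding = c("paper", "exact")) {
  rounding <- match.arg(rounding)
  algs <- unique(decisions$algorithm)
  out <- lapply(algs, function(a) {
    compute_metrics(build_confusion_matrix(decisions[decisions$algorithm == a, ],
                                           cohort), rounding)
  })
  names(out) <- algs
  out
}

#' Pairwise imaging-burden and missed-diagnosis difference
#'
#' Difference (a minus b) in the number of patients sent to imaging and in
#' missed diagnoses between two algorithms evaluated on the same cohort,
#' with each difference also expressed as a percentage of the cohort size
#' (rounded half-up to one decimal). The missed-diagnosis comparison is
#' flagged not applicable when either side's missed count is unobservable.
#'
#' @param metrics_a,metrics_b `dta_metrics` panels from the same cohort.
#' @param n_total cohort size the percentages are computed against.
#' @return a one-row tibble with columns `algorithm_a`, `algorithm_b`,
#'   `imaging_diff`, `imaging_diff_pct`, `missed_diff`, `missed_diff_pct`,
#'   `not_applicable_missed`.
#' @export
pairwise_difference <- function(metrics_a, metrics_b, n_total) {
  stopifnot(inherits(metrics_a, "dta_metrics"), inherits(metrics_b, "dta_metrics"))
  if (!is.numeric(n_total) || n_total <= 0) stop2("n_total must be positive")
  img <- metrics_a$imaging_count - metrics_b$imaging_count
  na_missed <- is.na(metrics_a$missed_count) || is.na(metrics_b$missed_count)
  missed <- if (na_missed) NA_integer_ else metrics_a$missed_count - metrics_b$missed_count
  tibble(
    algorithm_a = metrics_a$algorithm, algorithm_b = metrics_b$algorithm,
    imaging_diff = img,
    imaging_diff_pct = round_half_up(100 * img / n_total, 1),
    missed_diff = missed,
    missed_diff_pct = if (na_missed) NA_real_ else round_half_up(100 * missed / n_total, 1),
    not_applicable_missed = na_missed
  )
}

#' All pairwise differences between evaluated algorithms
#'
#' @param metrics a named list of `dta_metrics` (e.g. from
#'   [evaluate_decisions()]).
#' @param n_total cohort size.
#' @param pairs optional two-column matrix/data frame of (a, b) algorithm
#'   names; defaults to every unordered pair, better-ranked algorithm
#'   first, in the canonical reporting order when the five standard
#'   engines are present.
#' @return a tibble with one [pairwise_difference()] row per pair.
#' @export
pairwise_table <- function(metrics, n_total, pairs = NULL) {
  nm <- names(metrics)
  if (is.null(pairs)) {
    canonical <- c("peged", "years", "age_adjusted", "perc", "standard")
    ord <- if (setequal(nm, canonical)) canonical else nm
    cmb <- utils::combn(ord, 2)
    pairs <- data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pairwise_difference(metrics[[pairs[i, 1]]], metrics[[pairs[i, 2]]], n_total)
  })
  do.call(rbind, rows)
}

#' Welch t-test from summary statistics
#'
#' Two-sample t-test computed from group means, standard deviations and
#' sizes (for published tables that report only mean +/- SD). `var_equal =
#' TRUE` gives the pooled (Student) test instead of Welch.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param var_equal pooled-variance test if `TRUE`.
#' @return a list with `statistic`, `df`, `p_value`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, var_equal = FALSE) {
  if (n1 < 2 || n2 < 2) stop2("each group needs at least 2 observations")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test from 2x2 counts
#'
#' Pearson chi-square (1 df, no continuity correction by default) comparing
#' an event rate between two groups given the event counts and group sizes.
#'
#' @param yes_a,n_a events and size in group A.
#' @param yes_b,n_b events and size in group B.
#' @param correct apply the Yates continuity correction.
#' @return the `htest` object from [stats::chisq.test()].
#' @export
chisq_from_counts <- function(yes_a, n_a, yes_b, n_b, correct = FALSE) {
  m <- matrix(c(yes_a, n_a - yes_a, yes_b, n_b - yes_b), nrow = 2)
  stats::chisq.test(m, correct = correct)
}

#' Between-group cohort characteristics table
#'
#' Splits the cohort by `confirmed_pe` and compares every clinical field
#' between the PE-absent and PE-present groups: continuous fields (age,
#' BODE index, D-dimer, heart rate, SaO2 and the computed Wells score) as
#' mean +/- SD with a two-sample t-test; boolean fields (the clinical items
#' plus the derived indicators age < 50, HR > 100, SaO2 <= 94 and the
#' two-level "PE likely" category) as n (%) with a Pearson chi-square test
#' without continuity correction.
#'
#' @param cohort a `pe_cohort` with `confirmed_pe` for every patient.
#' @param config a [triage_config()] supplying the Wells weights and C-PTP
#'   scheme for the derived rows.
#' @param var_equal use the pooled-variance t-test (default Welch).
#' @return a tibble with columns `variable`, `type`, `no_pe`, `pe`
#'   (formatted group summaries), `p_value`, `computable`.
#' @export
compare_groups <- function(cohort, config = triage_config(), var_equal = FALSE) {
  require_truth(cohort)
  g <- cohort$confirmed_pe
  n0 <- sum(!g); n1 <- sum(g)
  if (n0 == 0 || n1 == 0) stop2("both PE-absent and PE-present groups must be non-empty")
  score <- compute_wells_score(cohort, config$wells)

  cont_row <- function(name, x) {
    x0 <- x[!g]; x1 <- x[g]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    computable <- length(x0) >= 2 && length(x1) >= 2 &&
      (stats::sd(x0) > 0 || stats::sd(x1) > 0)
    p <- if (computable) {
      stats::t.test(x0, x1, var.equal = var_equal)$p.value
    } else NA_real_
    tibble(variable = name, type = "continuous",
           no_pe = sprintf("%.1f ± %.1f", mean(x0), stats::sd(x0)),
           pe = sprintf("%.1f ± %.1f", mean(x1), stats::sd(x1)),
           p_value = p, computable = computable)
  }
  bin_row <- function(name, x) {
    k0 <- sum(x[!g]); k1 <- sum(x[g])
    computable <- n0 > 0 && n1 > 0
    p <- if (computable) {
      suppressWarnings(chisq_from_counts(k0, n0, k1, n1)$p.value)
    } else NA_real_
    tibble(variable = name, type = "binary",
           no_pe = sprintf("%d (%.1f)", k0, 100 * k0 / n0),
           pe = sprintf("%d (%.1f)", k1, 100 * k1 / n1),
           p_value = p, computable = computable)
  }

  cont <- list(
    cont_row("age", cohort$age),
    if (!all(is.na(cohort$bode_index))) cont_row("bode_index", cohort$bode_index),
    cont_row("d_dimer", cohort$d_dimer),
    cont_row("heart_rate", cohort$heart_rate),
    cont_row("sao2", cohort$sao2),
    cont_row("wells_score", score)
  )
  bins <- c(
    list(bin_row("age_lt_50", cohort$age < 50)),
    lapply(.boolean_cols, function(col) bin_row(col, cohort[[col]])),
    list(bin_row("hr_gt_100", cohort$heart_rate > 100),
         bin_row("sao2_le_94", cohort$sao2 <= 94),
         bin_row("pe_likely", cptp_two_level(score, config$scheme) == "pe_likely"))
  )
  do.call(rbind, c(cont[!vapply(cont, is.null, logical(1))], bins))
}

#' Render an evaluation report
#'
#' Deterministic, byte-stable rendering of per-algorithm metric panels and
#' pairwise comparisons, with the C-PTP scheme and rounding convention in
#' the header.
#'
#' @param metrics a named list of `dta_metrics`.
#' @param comparisons optional tibble from [pairwise_table()].
#' @param format `"markdown"`, `"tsv"` or `"json"`.
#' @param scheme the [cptp_scheme()] used (named in the header).
#' @return a single character string.
#' @export
render_report <- function(metrics, comparisons = NULL,
                          format = c("markdown", "tsv", "json"),
                          scheme = cptp_scheme()) {
  format <- match.arg(format)
  if (!length(metrics)) stop2("at least one evaluated algorithm is required")
  rounding <- metrics[[1]]$rounding
  fmt <- function(v, d) ifelse(is.na(v), "N/A", formatC(v, format = "f", digits = d))
  metric_tbl <- do.call(rbind, lapply(metrics, function(m) {
    tibble(algorithm = m$algorithm, tp = m$tp, fp = m$fp,
           fn = m$fn, tn = m$tn,
           sensitivity = m$sensitivity, specificity = m$specificity,
           ppv = m$ppv, npv = m$npv, plr = m$plr, nlr = m$nlr,
           youden = m$youden, accuracy = m$accuracy,
           imaging = m$imaging_count, missed = m$missed_count)
  }))

  if (format == "json") {
    return(jsonlite::toJSON(
      list(cptp_scheme = scheme$preset, rounding = rounding,
           metrics = metric_tbl, comparisons = comparisons),
      dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA, pretty = TRUE
    ))
  }

  if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    writeLines(sprintf("# cptp_scheme=%s rounding=%s", scheme$preset, rounding), con)
    utils::write.table(metric_tbl, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "N/A")
    if (!is.null(comparisons) && nrow(comparisons)) {
      writeLines("", con)
      utils::write.table(comparisons, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "N/A")
    }
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }

  # markdown
  lines <- c(
    "# PE triage evaluation report",
    "",
    sprintf("C-PTP scheme: %s; rounding convention: %s", scheme$preset, rounding),
    "",
    "## Diagnostic accuracy",
    "",
    paste("| algorithm | TP | FP | FN | TN | Sens % | Spec % | PPV % | NPV %",
          "| PLR | NLR | YI | DA % | imaging | missed |"),
    paste0("|", paste(rep("---|", 15), collapse = ""))
  )
  for (i in seq_len(nrow(metric_tbl))) {
    r <- metric_tbl[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d | %d | %s | %s | %s | %s | %s | %s | %s | %s | %s | %s | %d | %s |",
      r$algorithm, r$tp, r$fp, fmt(r$fn, 0), fmt(r$tn, 0),
      fmt(r$sensitivity, 1), fmt(r$specificity, 1), fmt(r$ppv, 1), fmt(r$npv, 1),
      fmt(r$plr, 3), fmt(r$nlr, 3), fmt(r$youden, 3), fmt(r$accuracy, 1),
      r$imaging, fmt(r$missed, 0)))
  }
  if (!is.null(comparisons) && nrow(comparisons)) {
    lines <- c(lines, "", "## Pairwise differences", "",
               "| comparison | imaging diff (%) | missed diff (%) |",
               "|---|---|---|")
    for (i in seq_len(nrow(comparisons))) {
      r <- comparisons[i, ]
      lines <- c(lines, sprintf(
        "| %s - %s | %d (%s) | %s |",
        r$algorithm_a, r$algorithm_b, r$imaging_diff, fmt(r$imaging_diff_pct, 1),
        if (r$not_applicable_missed) "N/A"
        else sprintf("%d (%s)", r$missed_diff, fmt(r$missed_diff_pct, 1))))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
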