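read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "petriage", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reference study counts and published panel
#'
#' The packaged 2x2 counts (TP/FP/FN/TN) of the five triage algorithms in
#' the reference AECOPD cohort of 1158 patients (210 with confirmed PE).
#' The Standard algorithm defined the imaging set of that cohort, so its
#' FN/TN cells are unobservable and stored as `NA`.
#'
#' @return a tibble with columns `algorithm`, `tp`, `fp`, `fn`, `tn`.
#' @export
reference_counts <- function() read_extdata("reference_counts.csv")

#' Recompute the reference accuracy and comparison tables
#'
#' Feeds the packaged reference counts ([reference_counts()]) through
#' [compute_metrics()] and [pairwise_table()] and diffs the result against
#' the published panel, metric by metric. One known single-digit
#' discrepancy is expected: the published age-adjusted PLR is 3.034 while
#' both rounding routes of 0.786/0.259 give 3.035 (the published figure
#' appears truncated); the diff flags it rather than hiding it.
#'
#' @param rounding rounding convention passed to [compute_metrics()];
#'   `"paper"` reproduces the published panel.
#' @return a list with
#'   \describe{
#'     \item{metrics}{named list of `dta_metrics`, one per algorithm.}
#'     \item{metric_table}{tibble of the recomputed eight-metric panel.}
#'     \item{pairwise}{tibble of all ten pairwise imaging / missed
#'       differences.}
#'     \item{imaging_counts, missed_counts}{named vectors of patients sent
#'       to imaging and missed diagnoses per algorithm.}
#'     \item{diff}{machine-readable comparison of every recomputed value
#'       against the published one (`algorithm`, `metric`, `computed`,
#'       `expected`, `match`).}
#'   }
#' @export
reproduce_reference_tables <- function(rounding = "paper") {
  counts <- reference_counts()
  n_total <- sum(counts$tp[counts$algorithm == "standard"],
                 counts$fp[counts$algorithm == "standard"])

  metrics <- lapply(seq_len(nrow(counts)), function(i) {
    compute_metrics(pe_confusion(counts$tp[i], counts$fp[i], counts$fn[i],
                                 counts$tn[i], algorithm = counts$algorithm[i]),
                    rounding = rounding)
  })
  names(metrics) <- counts$algorithm

  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "plr", "nlr",
                   "youden", "accuracy")
  metric_table <- do.call(rbind, lapply(metrics, function(m) {
    tibble(algorithm = m$algorithm,
           sensitivity = m$sensitivity, specificity = m$specificity,
           ppv = m$ppv, npv = m$npv, plr = m$plr, nlr = m$nlr,
           youden = m$youden, accuracy = m$accuracy,
           imaging = m$imaging_count, missed = m$missed_count)
  }))

  pairwise <- pairwise_table(metrics, n_total)

  expected <- read_extdata("reference_metrics.csv")
  diff <- do.call(rbind, lapply(seq_len(nrow(expected)), function(i) {
    alg <- expected$algorithm[i]
    do.call(rbind, lapply(c(metric_cols, "imaging", "missed"), function(mc) {
      comp <- metric_table[[mc]][metric_table$algorithm == alg]
      exp <- expected[[mc]][i]
      tibble(algorithm = alg, metric = mc, computed = comp, expected = exp,
             match = (is.na(comp) && is.na(exp)) ||
               (!is.na(comp) && !is.na(exp) && isTRUE(all.equal(comp, exp))))
    }))
  }))

  list(
    metrics = metrics,
    metric_table = metric_table,
    pairwise = pairwise,
    imaging_counts = stats::setNames(metric_table$imaging, metric_table$algorithm),
    missed_counts = stats::setNames(metric_table$missed, metric_table$algorithm),
    diff = diff
  )
}

#' Run the full simulate / triage / evaluate / compare pipeline
#'
#' Generates (or accepts) a cohort, runs the requested triage engines,
#' scores them against the reference standard and computes all pairwise
#' comparisons. Fully deterministic given the simulation seed. When
#' `output_dir` is supplied, the cohort, decision table, metric panel
#' (JSON) and a markdown report are written there.
#'
#' @param sim_config a [cohort_sim_config()], or `NULL` when `cohort` is
#'   supplied.
#' @param cohort an existing `pe_cohort` with truth labels; overrides
#'   `sim_config`.
#' @param config a [triage_config()].
#' @param algorithms engines to run; see [pe_algorithms()].
#' @param rounding convention for [compute_metrics()].
#' @param output_dir optional directory for the report bundle.
#' @return a list with `cohort`, `decisions`, `metrics`, `comparisons`,
#'   `report` (markdown string) and, when simulated, `validation` (the
#'   [validate_marginals()] table).
#' @export
run_pe_pipeline <- function(sim_config = cohort_sim_config(), cohort = NULL,
                            config = triage_config(),
                            algorithms = pe_algorithms(),
                            rounding = c("paper", "exact"),
                            output_dir = NULL) {
  rounding <- match.arg(rounding)
  simulated <- is.null(cohort)
  if (simulated) {
    if (is.null(sim_config)) stop2("no cohort source: supply sim_config or cohort")
    cohort <- generate_cohort(sim_config)
  }
  require_truth(cohort)
  decisions <- triage_cohort(cohort, config, algorithms)
  metrics <- evaluate_decisions(decisions, cohort, rounding)
  comparisons <- if (length(metrics) >= 2) {
    pairwise_table(metrics, nrow(cohort))
  } else NULL
  report <- render_report(metrics, comparisons, format = "markdown",
                          scheme = config$scheme)
  validation <- if (simulated) validate_marginals(cohort, sim_config) else NULL

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    readr::write_csv(decisions, file.path(output_dir, "decisions.csv"), na = "")
    writeLines(render_report(metrics, comparisons, format = "json",
                             scheme = config$scheme),
               file.path(output_dir, "metrics.json"))
    writeLines(report, file.path(output_dir, "report.md"), sep = "")
  }

  list(cohort = cohort, decisions = decisions, metrics = metrics,
       comparisons = comparisons, report = report, validation = validation)
}
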