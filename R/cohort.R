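#' @importFrom tibble tibble as_tibble
#' @importFrom readr read_csv write_csv cols col_character
NULL

# column schema for a patient cohort table
.numeric_cols <- c("age", "heart_rate", "sao2", "d_dimer")
.boolean_cols <- c(
  "dvt_signs", "pe_most_likely", "hemoptysis", "recent_immobilization",
  "recent_surgery", "recent_trauma", "history_vte", "active_cancer",
  "oral_hormone_use", "unilateral_leg_swelling"
)
.required_cols <- c("patient_id", .numeric_cols, .boolean_cols)
.optional_cols <- c("bode_index", "confirmed_pe")

.true_tokens <- c("1", "true", "yes")
.false_tokens <- c("0", "false", "no")

new_pe_cohort <- function(df, source = "in-memory") {
  out <- as_tibble(df)
  attr(out, "source") <- source
  class(out) <- unique(c("pe_cohort", class(out)))
  out
}

# range / type checks shared by read_cohort() and the generator.
# Returns a character vector of problems ("row i, column x: message"),
# empty when the table is valid.
cohort_problems <- function(df) {
  probs <- character(0)
  bad <- function(rows, col, msg) {
    if (any(rows)) sprintf("row %d, column '%s': %s", which(rows), col, msg)
  }
  probs <- c(
    probs,
    bad(is.na(df$age) | df$age < 0, "age", "must be a number >= 0"),
    bad(is.na(df$heart_rate) | df$heart_rate <= 0, "heart_rate", "must be a number > 0"),
    bad(is.na(df$sao2) | df$sao2 < 0 | df$sao2 > 100, "sao2", "must be in [0, 100]"),
    bad(is.na(df$d_dimer) | df$d_dimer < 0, "d_dimer", "must be a number >= 0 (ng/ml)")
  )
  for (col in .boolean_cols) {
    probs <- c(probs, bad(is.na(df[[col]]), col, "must be one of 1/0, true/false, yes/no"))
  }
  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    probs <- c(probs, sprintf(
      "duplicate patient_id '%s' (row %d)", df$patient_id[dup], which(dup)
    ))
  }
  probs
}

parse_boolean <- function(x, col) {
  tok <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[tok %in% .true_tokens] <- TRUE
  out[tok %in% .false_tokens] <- FALSE
  # tokens that are neither empty nor recognisably boolean stay NA and are
  # reported by cohort_problems() with their row number
  out
}

#' Read a patient cohort from CSV
#'
#' Reads one row per patient with demographics, vitals, D-dimer (ng/ml),
#' the boolean clinical items consumed by the triage rules, and the optional
#' `bode_index` and `confirmed_pe` columns. Column matching is
#' case-insensitive; booleans accept `1/0`, `true/false`, `yes/no` in any
#' case. All rows are validated before anything is returned: out-of-range
#' values, unparseable cells and duplicate `patient_id`s raise an error
#' naming every offending row and column.
#'
#' @param path path to a CSV file with a header row.
#' @param d_dimer_unit unit of the `d_dimer` column in the file. Values are
#'   stored in ng/ml; `"ug_ml"` multiplies by 1000 on ingest.
#' @return a `pe_cohort` tibble, one validated row per patient, in file order.
#'   Missing optional columns are absent-as-`NA`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, d_dimer_unit = c("ng_ml", "ug_ml")) {
  d_dimer_unit <- match.arg(d_dimer_unit)
  if (!file.exists(path)) stop2("cohort file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop2("cohort schema error: missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  blank <- function(x) is.na(x) | trimws(x) == ""

  num <- function(col) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- !blank(x) & is.na(v)
    if (any(bad)) {
      stop2("cohort parse error: ", paste(
        sprintf("row %d, column '%s': cannot parse '%s' as a number",
                which(bad), col, x[bad]), collapse = "; "))
    }
    v
  }

  df <- tibble(patient_id = raw$patient_id)
  for (col in .numeric_cols) df[[col]] <- num(col)
  for (col in .boolean_cols) df[[col]] <- parse_boolean(raw[[col]], col)
  df$bode_index <- if ("bode_index" %in% names(raw)) num("bode_index") else NA_real_
  df$confirmed_pe <- if ("confirmed_pe" %in% names(raw)) {
    parse_boolean(raw$confirmed_pe, "confirmed_pe")
  } else NA
  if (d_dimer_unit == "ug_ml") df$d_dimer <- df$d_dimer * 1000

  probs <- cohort_problems(df)
  if (length(probs)) stop2("cohort validation error: ", paste(probs, collapse = "; "))
  new_pe_cohort(df, source = path)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: booleans are serialised as `true`/`false`,
#' numbers with enough digits to round-trip exactly, absent optional values
#' as empty cells. `read_cohort(write_cohort(x, f))` reproduces `x`
#' field-for-field.
#'
#' @param cohort a non-empty `pe_cohort` (or data frame with the cohort columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) == 0L) stop2("cannot write an empty cohort")
  ser_bool <- function(x) ifelse(is.na(x), NA_character_, ifelse(x, "true", "false"))
  out <- tibble(patient_id = as.character(cohort$patient_id))
  for (col in .numeric_cols) out[[col]] <- format_exact(cohort[[col]])
  for (col in .boolean_cols) out[[col]] <- ser_bool(cohort[[col]])
  out$bode_index <- format_exact(cohort$bode_index %||% rep(NA_real_, nrow(cohort)))
  out$confirmed_pe <- ser_bool(cohort$confirmed_pe %||% rep(NA, nrow(cohort)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# cohorts entering evaluation must carry the reference standard
require_truth <- function(cohort) {
  if (is.null(cohort$confirmed_pe) || anyNA(cohort$confirmed_pe)) {
    missing <- if (is.null(cohort$confirmed_pe)) cohort$patient_id
               else cohort$patient_id[is.na(cohort$confirmed_pe)]
    stop2("confirmed_pe (reference standard) is required for evaluation; ",
          "missing for patient(s): ",
          paste(utils::head(missing, 5L), collapse = ", "),
          if (length(missing) > 5L) sprintf(" and %d more", length(missing) - 5L))
  }
  invisible(cohort)
}
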