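# Person-level cohort table: exposure (race_ethnicity), covariates, four
# categorized lifestyle mediators, and left-truncated survival on the age
# timescale (entry_age = age at survey, exit_age = age at death or censoring).

.cohort_columns <- c("subject_id", "race_ethnicity", "sex", "age_at_survey",
                     "education", "married", "survey_year",
                     "alcohol_category", "smoking_category", "bmi_category",
                     "activity_category", "entry_age", "exit_age", "event")

#' Validate a cohort table
#'
#' Enforces the analysis invariants: age at survey within \[18, 85\],
#' categorical fields on their defined level sets, positive follow-up
#' (exit_age > entry_age), event in \{0, 1\}, and complete cases. Rows
#' failing any check are dropped and counted in the validation report
#' (attribute \code{"validation"}). Records with race "other" are retained
#' but flagged: they enter descriptives, never the decomposition.
#'
#' @param data data.frame with the cohort columns (see \code{read_cohort})
#' @return a validated \code{cohort} data.frame; attributes
#'   \code{"validation"} (named drop counts) and flag column
#'   \code{in_decomposition}
#' @export
validate_cohort <- function(data) {
  missing_cols <- setdiff(.cohort_columns, names(data))
  if (length(missing_cols))
    .stop_domain("cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  d <- data[.cohort_columns]
  d$race_ethnicity <- .as_level(d$race_ethnicity, .race_levels)
  d$sex <- .as_level(d$sex, .sex_levels)
  d$education <- .as_level(d$education, .edu_levels)
  for (m in names(.mediator_levels))
    d[[m]] <- .as_level(d[[m]], .mediator_levels[[m]])
  d$married <- as.integer(d$married)
  d$event <- as.integer(d$event)
  d$survey_year <- as.integer(d$survey_year)

  n0 <- nrow(d)
  complete <- stats::complete.cases(d)
  age_ok <- !is.na(d$age_at_survey) & d$age_at_survey >= 18 & d$age_at_survey <= 85
  fup_ok <- !is.na(d$exit_age) & !is.na(d$entry_age) & d$exit_age > d$entry_age
  flag_ok <- d$married %in% c(0L, 1L) & d$event %in% c(0L, 1L)
  year_ok <- !is.na(d$survey_year) & d$survey_year >= 1997 & d$survey_year <= 2014
  keep <- complete & age_ok & fup_ok & flag_ok & year_ok
  keep[is.na(keep)] <- FALSE

  report <- c(n_input = n0,
              n_kept = sum(keep),
              dropped_incomplete = sum(!complete),
              dropped_age_bounds = sum(complete & !age_ok),
              dropped_followup = sum(complete & age_ok & !fup_ok),
              dropped_flags = sum(complete & age_ok & fup_ok & !(flag_ok & year_ok)))
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$in_decomposition <- out$race_ethnicity != "other"
  attr(out, "validation") <- report
  class(out) <- c("cohort", "data.frame")
  out
}

#' Read a person-level cohort from CSV
#'
#' Reads a header CSV (one row per subject), optionally renaming file columns
#' to the canonical cohort schema via \code{schema}, then validates with
#' \code{\link{validate_cohort}}. When \code{entry_age}/\code{exit_age} are
#' absent they are derived as \code{age_at_survey} and
#' \code{age_at_survey + followup_years}.
#'
#' @param path CSV file path
#' @param schema optional named character vector mapping canonical field
#'   names to file column names, e.g. \code{c(race_ethnicity = "RACE")}
#' @return validated \code{cohort} (see \code{\link{validate_cohort}})
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) .stop_domain("empty cohort file: ", path)
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent))
      .stop_domain("schema maps to column(s) absent from file: ",
                   paste(absent, collapse = ", "))
    for (canonical in names(schema))
      raw[[canonical]] <- raw[[schema[[canonical]]]]
  }
  if (!"entry_age" %in% names(raw) && "age_at_survey" %in% names(raw))
    raw$entry_age <- raw$age_at_survey
  if (!"exit_age" %in% names(raw) && "followup_years" %in% names(raw))
    raw$exit_age <- raw$entry_age + raw$followup_years
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    .stop_domain("cohort file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", "))
  validate_cohort(raw)
}

#' Write a cohort to CSV
#'
#' @param cohort validated cohort
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[.cohort_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  v <- attr(x, "validation")
  cat("Cohort:", nrow(x), "subjects,",
      sum(x$event), "deaths,",
      format(round(sum(x$exit_age - x$entry_age)), big.mark = ","),
      "person-years\n")
  if (!is.null(v))
    cat("Validation: kept", v[["n_kept"]], "of", v[["n_input"]], "records\n")
  cat("Race/ethnicity:", paste(sprintf("%s=%d", levels(x$race_ethnicity),
                                       tabulate(x$race_ethnicity, 4)),
                               collapse = " "), "\n")
  invisible(x)
}
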