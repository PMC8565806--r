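#' @importFrom rlang .data
NULL

# Controlled vocabularies for report fields. Any value outside these sets is
# coerced to "unknown" at ingest and recorded in the parse log; records are
# never dropped for a bad enum.
SEX_LEVELS       <- c("male", "female", "unknown")
CAUSALITY_LEVELS <- c("certain", "probable", "possible", "unlikely",
                      "unassessable", "unknown")
SEVERITY_LEVELS  <- c("serious", "non_serious")
NOVELTY_LEVELS   <- c("new", "known")
OUTCOME_LEVELS   <- c("recovered", "improved", "sequelae", "death", "unknown")
ROUTE_LEVELS     <- c("injection", "oral", "other", "unknown")

REPORT_COLUMNS <- c("report_id", "sex", "age_years", "drugs", "adr_terms",
                    "causality", "severity", "novelty", "outcome", "route",
                    "report_date")
OPTIONAL_COLUMNS <- c("allergy_history")

#' Construct a spontaneous-report table
#'
#' Builds a validated tibble of ADR case reports, one row per report.
#' Multi-valued fields (`drugs`, `adr_terms`) are list-columns of character
#' vectors. This is the in-memory form used throughout the package;
#' [read_reports()] and [write_reports()] convert to and from the delimited
#' on-disk form.
#'
#' @param report_id Character vector of unique report identifiers.
#' @param sex One of `"male"`, `"female"`, `"unknown"` per report.
#' @param age_years Integer age in whole years; `NA` for unknown.
#' @param drugs List of character vectors, each with at least one raw or
#'   canonical drug name.
#' @param adr_terms List of character vectors, each with at least one ADR
#'   term.
#' @param causality Reporter-assigned causality: `"certain"`, `"probable"`,
#'   `"possible"`, `"unlikely"`, `"unassessable"`, or `"unknown"`.
#' @param severity `"serious"` or `"non_serious"`.
#' @param novelty `"new"` (not in the product label) or `"known"`.
#' @param outcome `"recovered"`, `"improved"`, `"sequelae"`, `"death"`, or
#'   `"unknown"`.
#' @param route `"injection"`, `"oral"`, `"other"`, or `"unknown"`.
#' @param report_date `Date` vector; `NA` for unknown.
#' @param allergy_history Optional free-text allergy history; retained but
#'   not analysed.
#' @return A tibble with class `adr_reports`.
#' @export
adr_reports <- function(report_id, sex = "unknown", age_years = NA_integer_,
                        drugs, adr_terms,
                        causality = "unknown", severity = "non_serious",
                        novelty = "known", outcome = "unknown",
                        route = "unknown", report_date = as.Date(NA),
                        allergy_history = NA_character_) {
  if (!is.list(drugs)) drugs <- list(drugs)
  if (!is.list(adr_terms)) adr_terms <- list(adr_terms)
  out <- tibble::tibble(
    report_id = as.character(report_id),
    sex = sex, age_years = as.integer(age_years),
    drugs = drugs, adr_terms = adr_terms,
    causality = causality, severity = severity, novelty = novelty,
    outcome = outcome, route = route,
    report_date = as.Date(report_date),
    allergy_history = as.character(allergy_history)
  )
  validate_reports(out)
}

#' Validate a report table
#'
#' Checks the structural invariants of an `adr_reports` table: required
#' columns present, `report_id` unique, every report carries at least one
#' drug and one ADR term, ages non-negative, and all enum fields within
#' their controlled vocabularies.
#'
#' @param reports A report tibble.
#' @return The input, invisibly classed as `adr_reports`, or an error.
#' @export
validate_reports <- function(reports) {
  missing <- setdiff(REPORT_COLUMNS, names(reports))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(reports$report_id[duplicated(reports$report_id)])
  if (length(dup) > 0) {
    stop("duplicate report_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(reports$drugs) == 0)) {
    stop("every report must list at least one drug", call. = FALSE)
  }
  if (any(lengths(reports$adr_terms) == 0)) {
    stop("every report must list at least one ADR term", call. = FALSE)
  }
  ok_age <- is.na(reports$age_years) | reports$age_years >= 0
  if (!all(ok_age)) stop("age_years must be >= 0 or NA", call. = FALSE)
  enum_checks <- list(sex = SEX_LEVELS, causality = CAUSALITY_LEVELS,
                      severity = SEVERITY_LEVELS, novelty = NOVELTY_LEVELS,
                      outcome = OUTCOME_LEVELS, route = ROUTE_LEVELS)
  for (field in names(enum_checks)) {
    bad <- setdiff(unique(reports[[field]]), enum_checks[[field]])
    if (length(bad) > 0) {
      stop("invalid ", field, " value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  class(reports) <- unique(c("adr_reports", class(reports)))
  invisible(reports)
}

coerce_enum <- function(x, levels, field, report_id, log_env) {
  x[is.na(x) | !nzchar(x)] <- "unknown"
  bad <- !(x %in% levels)
  if (any(bad)) {
    log_env$log <- dplyr::bind_rows(
      log_env$log,
      tibble::tibble(report_id = report_id[bad], field = field,
                     raw_value = x[bad])
    )
    x[bad] <- "unknown"
  }
  x
}

#' Read a spontaneous-report table from CSV
#'
#' Reads a UTF-8, comma-separated report table with a mandatory header row.
#' Multi-valued `drugs` / `adr_terms` cells hold `";"`-separated entries.
#' Enum fields with unrecognised values are coerced to `"unknown"` and each
#' coercion is recorded in a parse log attached to the result (see
#' [parse_log()]); rows are never dropped at ingest.
#'
#' @param path Path to a CSV file.
#' @param multi_delim Delimiter separating entries inside a multi-valued
#'   cell (default `";"`).
#' @return An `adr_reports` tibble with a `parse_log` attribute.
#' @seealso [write_reports()] for the inverse; the two round-trip exactly.
#' @export
read_reports <- function(path, multi_delim = MULTI_DELIM) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(REPORT_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(raw$report_id[duplicated(raw$report_id)])
  if (length(dup) > 0) {
    stop("duplicate report_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  log_env <- new.env(parent = emptyenv())
  log_env$log <- tibble::tibble(report_id = character(),
                                field = character(),
                                raw_value = character())
  id <- raw$report_id

  age <- suppressWarnings(as.integer(raw$age_years))
  bad_age <- !is.na(raw$age_years) & nzchar(raw$age_years) &
    (is.na(age) | age < 0)
  if (any(bad_age)) {
    log_env$log <- dplyr::bind_rows(
      log_env$log,
      tibble::tibble(report_id = id[bad_age], field = "age_years",
                     raw_value = raw$age_years[bad_age])
    )
    age[bad_age] <- NA_integer_
  }

  dates <- suppressWarnings(as.Date(raw$report_date, format = "%Y-%m-%d"))
  bad_date <- !is.na(raw$report_date) & nzchar(raw$report_date) &
    is.na(dates)
  if (any(bad_date)) {
    log_env$log <- dplyr::bind_rows(
      log_env$log,
      tibble::tibble(report_id = id[bad_date], field = "report_date",
                     raw_value = raw$report_date[bad_date])
    )
  }

  out <- tibble::tibble(
    report_id = id,
    sex = coerce_enum(raw$sex, SEX_LEVELS, "sex", id, log_env),
    age_years = age,
    drugs = split_multi(raw$drugs, multi_delim),
    adr_terms = split_multi(raw$adr_terms, multi_delim),
    causality = coerce_enum(raw$causality, CAUSALITY_LEVELS, "causality",
                            id, log_env),
    severity = coerce_enum(raw$severity, SEVERITY_LEVELS, "severity",
                           id, log_env),
    novelty = coerce_enum(raw$novelty, NOVELTY_LEVELS, "novelty",
                          id, log_env),
    outcome = coerce_enum(raw$outcome, OUTCOME_LEVELS, "outcome",
                          id, log_env),
    route = coerce_enum(raw$route, ROUTE_LEVELS, "route", id, log_env),
    report_date = dates,
    allergy_history = if ("allergy_history" %in% names(raw)) {
      raw$allergy_history
    } else {
      NA_character_
    }
  )
  empty_drugs <- lengths(out$drugs) == 0
  empty_adrs <- lengths(out$adr_terms) == 0
  if (any(empty_drugs | empty_adrs)) {
    stop("report(s) with empty drugs or adr_terms: ",
         paste(id[empty_drugs | empty_adrs], collapse = ", "),
         call. = FALSE)
  }
  out <- validate_reports(out)
  attr(out, "parse_log") <- log_env$log
  out
}

#' Parse log of an ingested report table
#'
#' @param reports An `adr_reports` table returned by [read_reports()].
#' @return A tibble with one row per field value that was coerced to
#'   `"unknown"` (columns `report_id`, `field`, `raw_value`).
#' @export
parse_log <- function(reports) {
  attr(reports, "parse_log") %||%
    tibble::tibble(report_id = character(), field = character(),
                   raw_value = character())
}

#' Write a spontaneous-report table to CSV
#'
#' Serialises an `adr_reports` table to the package's on-disk dialect:
#' UTF-8 CSV, `"\n"` line endings, fixed column order, multi-valued fields
#' joined with `";"`, unknown ages and dates as empty cells. The writer is
#' byte-stable: identical input yields identical bytes, and
#' `read_reports(write_reports(x))` reproduces `x`.
#'
#' @param reports An `adr_reports` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  if (nrow(reports) > 0) validate_reports(reports)
  flat <- tibble::tibble(
    report_id = as.character(reports$report_id),
    sex = reports$sex,
    age_years = ifelse(is.na(reports$age_years), "",
                       as.character(reports$age_years)),
    drugs = join_multi(reports$drugs),
    adr_terms = join_multi(reports$adr_terms),
    causality = reports$causality,
    severity = reports$severity,
    novelty = reports$novelty,
    outcome = reports$outcome,
    route = reports$route,
    report_date = ifelse(is.na(reports$report_date), "",
                         format(reports$report_date, "%Y-%m-%d")),
    allergy_history = reports$allergy_history
  )
  if (nrow(flat) == 0) {
    flat <- flat[0, , drop = FALSE]
  }
  readr::write_csv(flat, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}
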