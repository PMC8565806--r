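#' Inclusion criteria for report selection
#'
#' Encodes the selection rules applied before signal mining: a pediatric
#' age window, the reporter-assigned causality levels retained (by
#' convention the certain/probable/possible upper three of the Chinese SRS
#' six-level scale), and optionally a restriction to a set of canonical
#' drug names (e.g. one drug class).
#'
#' @param age_min,age_max Inclusive age window in whole years.
#' @param causality_allowed Character vector of retained causality levels;
#'   must be non-empty.
#' @param drug_class_filter Optional character vector of canonical drug
#'   names; when set, a report must name at least one of them.
#' @param unknown_age `"exclude"` (default) removes unknown-age reports
#'   with their own reason code so they can be tallied separately;
#'   `"include"` keeps them in the included set (they still drop out of
#'   age-stratified tables downstream).
#' @return An `inclusion_criteria` object.
#' @export
inclusion_criteria <- function(age_min = 0, age_max = 14,
                               causality_allowed = c("certain", "probable",
                                                     "possible"),
                               drug_class_filter = NULL,
                               unknown_age = c("exclude", "include")) {
  unknown_age <- match.arg(unknown_age)
  stopifnot(age_min <= age_max, length(causality_allowed) > 0)
  bad <- setdiff(causality_allowed, CAUSALITY_LEVELS)
  if (length(bad) > 0) {
    stop("unknown causality level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(age_min = age_min, age_max = age_max,
         causality_allowed = causality_allowed,
         drug_class_filter = drug_class_filter,
         unknown_age = unknown_age),
    class = "inclusion_criteria"
  )
}

#' Normalise drug names and ADR terms in a report table
#'
#' Maps every raw drug name to its canonical generic name and every raw
#' ADR string to its preferred term, then removes within-report duplicates
#' created by the mapping. Names absent from a dictionary are kept verbatim
#' and recorded in the normalisation log (attribute `"norm_log"`), never
#' dropped — an unmapped name is a dictionary gap, not a reason to lose a
#' report.
#'
#' @param reports An `adr_reports` table.
#' @param drug_dict A [drug_dictionary()].
#' @param adr_dict An [adr_dictionary()].
#' @return The report table with normalised `drugs` and `adr_terms`; the
#'   unmapped-name log is available via `attr(x, "norm_log")`.
#' @export
normalize_reports <- function(reports, drug_dict, adr_dict) {
  validate_reports(reports)
  log <- tibble::tibble(report_id = character(), field = character(),
                        raw_value = character())
  map_col <- function(values, ids, lookup, field) {
    flat <- unlist(values, use.names = FALSE)
    n <- lengths(values)
    rep_ids <- rep(ids, n)
    mapped <- lookup(flat)
    unmapped <- is.na(mapped)
    if (any(unmapped)) {
      log <<- dplyr::bind_rows(log, tibble::tibble(
        report_id = rep_ids[unmapped], field = field,
        raw_value = flat[unmapped]
      ))
      mapped[unmapped] <- flat[unmapped]
    }
    lapply(split(mapped, factor(rep_ids, levels = ids)), unique)
  }
  out <- reports
  out$drugs <- unname(map_col(reports$drugs, reports$report_id,
                              function(x) canonical_drug(drug_dict, x),
                              "drug"))
  out$adr_terms <- unname(map_col(reports$adr_terms, reports$report_id,
                                  function(x) preferred_term(adr_dict, x),
                                  "adr_term"))
  attr(out, "norm_log") <- log
  out
}

#' Partition reports into included and excluded sets
#'
#' Applies [inclusion_criteria()] to a normalised report table. Every
#' excluded report carries a machine-readable reason code: `"age"` (known
#' age outside the window), `"age_unknown"`, `"causality"`, or `"drug"`.
#' When several rules fail, the first in that order is recorded. The two
#' output sets partition the input exactly.
#'
#' @param reports An `adr_reports` table (normalised).
#' @param criteria An [inclusion_criteria()] object.
#' @return A list with `included` (report table) and `excluded` (report
#'   table plus a `reason` column).
#' @export
filter_reports <- function(reports, criteria) {
  stopifnot(inherits(criteria, "inclusion_criteria"))
  age <- reports$age_years
  age_known_bad <- !is.na(age) & (age < criteria$age_min |
                                    age > criteria$age_max)
  age_unknown_bad <- is.na(age) & criteria$unknown_age == "exclude"
  causality_bad <- !(reports$causality %in% criteria$causality_allowed)
  if (is.null(criteria$drug_class_filter)) {
    drug_bad <- rep(FALSE, nrow(reports))
  } else {
    drug_bad <- !vapply(reports$drugs, function(d) {
      any(d %in% criteria$drug_class_filter)
    }, logical(1))
  }
  reason <- rep(NA_character_, nrow(reports))
  reason[drug_bad] <- "drug"
  reason[causality_bad] <- "causality"
  reason[age_unknown_bad] <- "age_unknown"
  reason[age_known_bad] <- "age"
  excluded <- reports[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(included = reports[is.na(reason), , drop = FALSE],
       excluded = excluded)
}

#' Expand reports into drug-event combinations
#'
#' Converts each report into its drug-event combinations (DECs): one row
#' per distinct (report, drug, ADR term) triple, the counting unit of
#' disproportionality analysis. A report listing several suspected drugs
#' contributes each of its ADR terms once per drug; the same pair repeated
#' within one report counts once when `dedup = TRUE` (the default).
#'
#' The result is deterministically sorted by (report_id, drug, adr), so the
#' expansion is order-independent.
#'
#' @param reports An `adr_reports` table (normalised and filtered).
#' @param dedup Collapse repeated identical (drug, adr) pairs within a
#'   report (default `TRUE`).
#' @return A tibble of events with columns `report_id`, `drug`, `adr`.
#' @export
expand_events <- function(reports, dedup = TRUE) {
  if (nrow(reports) == 0) {
    return(tibble::tibble(report_id = character(), drug = character(),
                          adr = character()))
  }
  n_drugs <- lengths(reports$drugs)
  n_adrs <- lengths(reports$adr_terms)
  events <- tibble::tibble(
    report_id = rep(reports$report_id, n_drugs * n_adrs),
    drug = unlist(lapply(seq_len(nrow(reports)), function(i) {
      rep(reports$drugs[[i]], each = n_adrs[i])
    }), use.names = FALSE),
    adr = unlist(lapply(seq_len(nrow(reports)), function(i) {
      rep(reports$adr_terms[[i]], times = n_drugs[i])
    }), use.names = FALSE)
  )
  if (dedup) {
    events <- dplyr::distinct(events)
  }
  dplyr::arrange(events, .data$report_id, .data$drug, .data$adr)
}
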