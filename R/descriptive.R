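#' Frequency table with percentages
#'
#' Builds the standard SRS summary table: label, count, percent of an
#' explicit denominator, and cumulative percent. Percents are rounded half
#' up to two decimals, the precision at which such tables are printed.
#' The denominator is carried explicitly because report-level statistics
#' (denominator = number of reports) and event-level statistics
#' (denominator = number of drug-event combinations) coexist in the same
#' analysis and must not be conflated.
#'
#' @param labels Character vector of row labels.
#' @param counts Integer vector of counts, same length as `labels`.
#' @param denominator Total used for percentages; defaults to
#'   `sum(counts)`.
#' @param sort `"by_count_desc"` (default) or `"as_given"`.
#' @return A tibble with columns `label`, `count`, `percent`,
#'   `cumulative_percent`, and attribute `denominator`.
#' @export
frequency_table <- function(labels, counts, denominator = sum(counts),
                            sort = c("by_count_desc", "as_given")) {
  sort <- match.arg(sort)
  stopifnot(length(labels) == length(counts), all(counts >= 0),
            sum(counts) <= denominator)
  out <- tibble::tibble(label = as.character(labels),
                        count = as.integer(counts))
  if (sort == "by_count_desc") {
    out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$label)
  }
  out$percent <- round_half_up(out$count / denominator * 100, 2)
  out$cumulative_percent <-
    round_half_up(cumsum(out$count) / denominator * 100, 2)
  attr(out, "denominator") <- as.integer(denominator)
  out
}

#' Sex distribution and male-female ratio
#'
#' @param reports An `adr_reports` table.
#' @return A list with `n_male`, `n_female`, `n_unknown`, and `ratio`
#'   (males per female, two decimals; `NA` with `ratio_defined = FALSE`
#'   when there are no female reports).
#' @export
sex_summary <- function(reports) {
  n_male <- sum(reports$sex == "male")
  n_female <- sum(reports$sex == "female")
  n_unknown <- sum(reports$sex == "unknown")
  defined <- n_female > 0
  list(
    n_male = n_male, n_female = n_female, n_unknown = n_unknown,
    ratio = if (defined) round_half_up(n_male / n_female, 2) else NA_real_,
    ratio_defined = defined
  )
}

#' Overall severity and novelty breakdown
#'
#' Serious and non-serious reports partition the total; within each, the
#' novelty split separates ADRs not yet recorded in the product label
#' ("new") from documented ones.
#'
#' @param reports An `adr_reports` table.
#' @return A list with counts (`n_serious`, `n_non_serious`, `n_total`,
#'   `n_new_serious`, `n_new_non_serious`) and two-decimal percentages
#'   (`percent_serious`, `percent_non_serious`).
#' @export
severity_summary <- function(reports) {
  serious <- reports$severity == "serious"
  new <- reports$novelty == "new"
  n <- nrow(reports)
  list(
    n_serious = sum(serious),
    n_non_serious = sum(!serious),
    n_total = n,
    n_new_serious = sum(new & serious),
    n_new_non_serious = sum(new & !serious),
    percent_serious = round_half_up(sum(serious) / n * 100, 2),
    percent_non_serious = round_half_up(sum(!serious) / n * 100, 2)
  )
}

#' Named age-group presets
#'
#' `"single_year"` bins ages 0..14 one year at a time; `"under5_vs_over"`
#' is the 0-4 versus 5-14 dichotomy used to compare severity between young
#' children and older ones.
#'
#' @param age Integer vector of ages in years (`NA` = unknown).
#' @param preset `"single_year"` or `"under5_vs_over"`.
#' @return Character vector of group labels (`"unknown"` for `NA` ages).
#' @export
age_group <- function(age, preset = c("single_year", "under5_vs_over")) {
  preset <- match.arg(preset)
  out <- switch(preset,
    single_year = as.character(age),
    under5_vs_over = ifelse(age <= 4, "0-4", "5-14")
  )
  out[is.na(age)] <- "unknown"
  out
}

#' Severity breakdown by stratum
#'
#' Tabulates serious versus total reports within strata defined by sex,
#' age group, or suspected drug. In drug mode a report contributes to one
#' stratum per distinct suspected drug, and strata are ordered by total
#' report count descending — the conventional presentation of per-drug
#' serious-ADR tables.
#'
#' @param reports An `adr_reports` table.
#' @param stratifier `"sex"`, `"age_group"`, or `"drug"`.
#' @param age_preset Passed to [age_group()] when stratifying by age.
#' @return A tibble with columns `stratum`, `n_serious`, `n_total`,
#'   `percent_serious` (two decimals).
#' @export
severity_by_stratum <- function(reports,
                                stratifier = c("sex", "age_group", "drug"),
                                age_preset = "single_year") {
  stratifier <- match.arg(stratifier)
  if (stratifier == "drug") {
    df <- tibble::tibble(
      stratum = unlist(lapply(reports$drugs, unique), use.names = FALSE),
      serious = rep(reports$severity == "serious",
                    vapply(reports$drugs, function(d) length(unique(d)),
                           integer(1)))
    )
  } else {
    strata <- switch(stratifier,
      sex = reports$sex,
      age_group = age_group(reports$age_years, age_preset)
    )
    df <- tibble::tibble(stratum = strata,
                         serious = reports$severity == "serious")
  }
  out <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_serious = sum(.data$serious),
                     n_total = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(percent_serious =
                    round_half_up(.data$n_serious / .data$n_total * 100, 2))
  if (stratifier == "drug") {
    out <- dplyr::arrange(out, dplyr::desc(.data$n_total), .data$stratum)
  } else {
    out <- dplyr::arrange(out, .data$stratum)
  }
  out
}

#' Pearson chi-square test on an r x c count table
#'
#' The Pearson statistic with p-value from the chi-square distribution on
#' (r-1)(c-1) degrees of freedom. Yates' continuity correction is applied
#' only for 2 x 2 tables and only when requested; for larger tables the
#' flag is ignored, as the correction is defined only in the fourfold
#' case.
#'
#' @param table Matrix (or object coercible to one) of non-negative
#'   counts, at least 2 x 2.
#' @param yates Apply the continuity correction for 2 x 2 tables.
#' @return A list with `chi2`, `df`, and `p`.
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("table must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margin", call. = FALSE)
  }
  correct <- yates && nrow(m) == 2 && ncol(m) == 2
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' ADR frequency by preferred term or system-organ class
#'
#' Tabulates event counts per ADR preferred term, or per system-organ
#' class after mapping each term through the dictionary's SOC map. The
#' denominator is the total number of events. Terms missing from the SOC
#' map fall into an `"unclassified"` bucket rather than being dropped.
#'
#' @param events Event tibble from [expand_events()].
#' @param adr_dict An [adr_dictionary()]; required for `level = "soc"`.
#' @param level `"term"` or `"soc"`.
#' @return A [frequency_table()] ordered by count descending.
#' @export
adr_frequency <- function(events, adr_dict = NULL,
                          level = c("term", "soc")) {
  level <- match.arg(level)
  if (level == "soc") {
    if (is.null(adr_dict)) stop("adr_dict required for level = \"soc\"",
                                call. = FALSE)
    soc <- unname(adr_dict$soc_map[events$adr])
    soc[is.na(soc)] <- "unclassified"
    tab <- table(soc)
  } else {
    tab <- table(events$adr)
  }
  frequency_table(names(tab), as.integer(tab), denominator = nrow(events))
}

#' Outcome distribution and death-case extract
#'
#' @param reports An `adr_reports` table.
#' @return A list with `table` (outcome [frequency_table()] over all
#'   reports), `percent_recovered_or_improved`, and `deaths` — one row per
#'   fatal report with sex, age, and the suspected drug(s) and ADR
#'   term(s), the fields reviewed case by case for fatal outcomes.
#' @export
outcome_summary <- function(reports) {
  tab <- table(factor(reports$outcome, levels = OUTCOME_LEVELS))
  ft <- frequency_table(names(tab), as.integer(tab),
                        denominator = nrow(reports))
  fatal <- reports[reports$outcome == "death", , drop = FALSE]
  deaths <- tibble::tibble(
    report_id = fatal$report_id,
    sex = fatal$sex,
    age_years = fatal$age_years,
    drugs = join_multi(fatal$drugs),
    adr_terms = join_multi(fatal$adr_terms)
  )
  rec <- sum(reports$outcome %in% c("recovered", "improved"))
  list(
    table = ft,
    percent_recovered_or_improved =
      round_half_up(rec / nrow(reports) * 100, 2),
    deaths = deaths
  )
}

#' Route-of-administration distribution
#'
#' @param reports An `adr_reports` table.
#' @return A [frequency_table()] of administration routes over all
#'   reports.
#' @export
route_summary <- function(reports) {
  tab <- table(factor(reports$route, levels = ROUTE_LEVELS))
  tab <- tab[tab > 0]
  frequency_table(names(tab), as.integer(tab), denominator = nrow(reports))
}
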