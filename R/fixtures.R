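#' Packaged reference tables from a provincial pediatric cephalosporin
#' safety study
#'
#' Returns the package's bundled study tables: per-drug report and
#' serious-report counts for 37 cephalosporins, event counts by
#' system-organ class (top 10), event counts for the most frequent ADR
#' terms (top 95%), the four fatal cases, and the headline totals of the
#' study (report and event counts, sex and severity splits, route counts,
#' and published signal counts). These are transcriptions of printed
#' summary tables — the underlying case-level database is confidential —
#' so they serve as inputs for descriptive statistics and as the default
#' marginals of the synthetic report generator, not as raw data.
#'
#' @return A list with tibbles `drug_reports` (generation, drug, total,
#'   serious), `soc_events` (rank, soc, n), `adr_events` (adr, n),
#'   `deaths` (one row per fatal case), and `counts`, a named numeric
#'   vector of study totals.
#' @export
study_fixture <- function() {
  path <- function(f) system.file("extdata", f, package = "pvkit",
                                  mustWork = TRUE)
  read <- function(f, types) {
    readr::read_csv(path(f), col_types = types, progress = FALSE)
  }
  counts_tbl <- read("study_summary_counts.csv", "cd")
  list(
    drug_reports = read("study_drug_reports.csv", "ccii"),
    soc_events = read("study_soc_events.csv", "ici"),
    adr_events = read("study_adr_events.csv", "ci"),
    deaths = read("study_deaths.csv", "iciccnc"),
    counts = stats::setNames(counts_tbl$value, counts_tbl$key)
  )
}
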