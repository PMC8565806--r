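#' Run the full signal-mining pipeline
#'
#' Orchestrates ingest (read a report CSV or simulate one), dictionary
#' normalisation, inclusion filtering, event expansion, descriptive
#' tables, disproportionality mining with off-label flagging, and a run
#' manifest, writing every stage output under `out_dir`. Any stage
#' failure aborts with the stage name and cause.
#'
#' The configuration is a named list (or path to a YAML file) with:
#' \describe{
#'   \item{`reports`}{Path to a report CSV, or}
#'   \item{`simulate`}{List of [synthetic_config()] arguments (`implants`
#'     may be a list of `drug`/`adr`/`rate_ratio` records).}
#'   \item{`drug_dict`, `adr_dict`}{Optional dictionary CSV paths; when
#'     omitted and `simulate` is used, the default synthetic-catalog
#'     dictionaries apply.}
#'   \item{`labels`}{Optional on-label ADR CSV (`canonical`, `adr`) for
#'     off-label flagging.}
#'   \item{`criteria`}{Optional [inclusion_criteria()] arguments
#'     (`causality_allowed` as a character vector).}
#'   \item{`signals`}{Optional [signal_criteria()] arguments.}
#' }
#'
#' The manifest records input file hashes, the configuration snapshot,
#' the package version, and the per-stage count chain (reports in,
#' excluded by reason, included, events, combinations scored, signals
#' per method, consensus, off-label). It contains no timestamps, so a
#' fixed-seed run is byte-reproducible; wall-clock details go to the run
#' log instead.
#'
#' @param config Named list or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly, with output files under `out_dir`:
#'   `events.csv`, `describe/*.csv`, `signals.csv`, `manifest.json`,
#'   `excluded.csv`, `run.log`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "describe"), showWarnings = FALSE)
  log_lines <- character()
  log_stage <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  input_hashes <- list()

  # -- ingest ---------------------------------------------------------
  reports <- stage("ingest", {
    if (!is.null(config$reports)) {
      input_hashes[["reports"]] <- unname(tools::md5sum(config$reports))
      read_reports(config$reports)
    } else if (!is.null(config$simulate)) {
      sim <- config$simulate
      if (!is.null(sim$implants)) {
        sim$implants <- dplyr::bind_rows(lapply(sim$implants, tibble::as_tibble))
      }
      generate_reports(do.call(synthetic_config, sim))
    } else {
      stop("config must provide either 'reports' or 'simulate'")
    }
  })
  log_stage("ingest: ", nrow(reports), " reports")

  # -- normalise ------------------------------------------------------
  dicts <- stage("normalize", {
    if (!is.null(config$drug_dict) || !is.null(config$adr_dict)) {
      if (is.null(config$drug_dict) || is.null(config$adr_dict)) {
        stop("both drug_dict and adr_dict are required together")
      }
      input_hashes[["drug_dict"]] <- unname(tools::md5sum(config$drug_dict))
      input_hashes[["adr_dict"]] <- unname(tools::md5sum(config$adr_dict))
      list(drug_dict = load_dictionary(config$drug_dict,
                                       labels_path = config$labels),
           adr_dict = load_dictionary(config$adr_dict))
    } else if (!is.null(config$simulate)) {
      default_dictionaries()
    } else {
      NULL
    }
  })
  if (!is.null(dicts)) {
    reports <- stage("normalize",
                     normalize_reports(reports, dicts$drug_dict,
                                       dicts$adr_dict))
    log_stage("normalize: ", nrow(attr(reports, "norm_log")),
              " unmapped names kept verbatim")
  }

  # -- filter ---------------------------------------------------------
  crit <- stage("filter", do.call(inclusion_criteria,
                                  config$criteria %||% list()))
  split <- stage("filter", filter_reports(reports, crit))
  included <- split$included
  excluded <- split$excluded
  log_stage("filter: ", nrow(included), " included, ", nrow(excluded),
            " excluded")
  if (nrow(excluded) > 0) {
    ex_flat <- excluded
    ex_flat$drugs <- join_multi(ex_flat$drugs)
    ex_flat$adr_terms <- join_multi(ex_flat$adr_terms)
    readr::write_csv(ex_flat, file.path(out_dir, "excluded.csv"),
                     na = "", eol = "\n", progress = FALSE)
  }

  # -- expand ---------------------------------------------------------
  events <- stage("expand", expand_events(included))
  readr::write_csv(events, file.path(out_dir, "events.csv"), na = "",
                   eol = "\n", progress = FALSE)
  log_stage("expand: ", nrow(events), " events")

  # -- describe -------------------------------------------------------
  stage("describe", {
    write_tbl <- function(x, name) {
      readr::write_csv(x, file.path(out_dir, "describe", name), na = "",
                       eol = "\n", progress = FALSE)
    }
    sx <- sex_summary(included)
    sv <- severity_summary(included)
    write_tbl(tibble::as_tibble(sx[c("n_male", "n_female", "n_unknown",
                                     "ratio")]), "sex.csv")
    write_tbl(tibble::as_tibble(sv), "severity.csv")
    write_tbl(severity_by_stratum(included, "drug"),
              "severity_by_drug.csv")
    write_tbl(severity_by_stratum(included, "age_group"),
              "severity_by_age.csv")
    write_tbl(adr_frequency(events, level = "term"), "adr_terms.csv")
    if (!is.null(dicts)) {
      write_tbl(adr_frequency(events, dicts$adr_dict, level = "soc"),
                "adr_soc.csv")
    }
    oc <- outcome_summary(included)
    write_tbl(oc$table, "outcome.csv")
    write_tbl(oc$deaths, "deaths.csv")
    write_tbl(route_summary(included), "route.csv")
  })
  log_stage("describe: tables written")

  # -- signals --------------------------------------------------------
  sig_crit <- stage("signals", do.call(signal_criteria,
                                       config$signals %||% list()))
  signals <- stage("signals", mine_signals(events, sig_crit))
  if (!is.null(dicts) && length(dicts$drug_dict$label_adr_map) > 0) {
    signals <- off_label_flags(signals, dicts$drug_dict)
  } else {
    signals$off_label <- NA
  }
  readr::write_csv(signals, file.path(out_dir, "signals.csv"), na = "",
                   eol = "\n", progress = FALSE)
  log_stage("signals: ", sum(signals$consensus), " consensus of ",
            nrow(signals), " scored combinations")

  # -- manifest -------------------------------------------------------
  manifest <- list(
    tool = list(package = "pvkit",
                version = as.character(utils::packageVersion("pvkit"))),
    inputs = input_hashes,
    config = config,
    counts = list(
      reports_in = nrow(reports),
      excluded = nrow(excluded),
      excluded_by_reason = as.list(table(excluded$reason)),
      included = nrow(included),
      events = nrow(events),
      decs_scored = nrow(signals),
      signals_ror = sum(signals$flag_ror),
      signals_prr = sum(signals$flag_prr),
      signals_mhra = sum(signals$flag_mhra),
      consensus = sum(signals$consensus),
      off_label = sum(signals$off_label & signals$consensus,
                      na.rm = TRUE)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
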