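#' Drug-name dictionary
#'
#' Maps raw drug-name strings (trade names, salts, transliterations) onto
#' canonical generic (active pharmaceutical ingredient) names, and carries
#' optional per-drug metadata: cephalosporin generation and the set of
#' on-label ADR preferred terms used for off-label flagging.
#'
#' The synonym map is made idempotent on construction: every canonical name
#' also maps to itself, so normalisation is a single lookup and applying it
#' twice changes nothing.
#'
#' @param synonyms Tibble or data.frame with columns `synonym`, `canonical`.
#' @param generations Optional named character vector or two-column table
#'   (`canonical`, `generation`) with values `"1st"`, `"2nd"`, `"3rd"`,
#'   `"4th"`, or `"unknown"`.
#' @param labels Optional two-column table (`canonical`, `adr`) listing the
#'   ADR preferred terms on each drug's product label. Drugs absent from
#'   this table have unknown label status.
#' @return An object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(synonyms, generations = NULL, labels = NULL) {
  synonyms <- tibble::as_tibble(synonyms)
  stopifnot(all(c("synonym", "canonical") %in% names(synonyms)))
  synonyms <- dplyr::distinct(synonyms, .data$synonym, .data$canonical)
  conflict <- synonyms$synonym[duplicated(synonyms$synonym)]
  if (length(conflict) > 0) {
    stop("synonym(s) mapped to multiple canonical names: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(synonyms$canonical, synonyms$synonym)
  # force idempotence: canonicals map to themselves
  self <- setdiff(unname(map), names(map))
  map <- c(map, stats::setNames(self, self))
  # a canonical that is itself a synonym of something else is a cycle
  not_fixed <- unname(map[unname(map)]) != unname(map)
  if (any(not_fixed)) {
    stop("canonical name(s) are themselves synonyms (cycle): ",
         paste(unique(unname(map)[not_fixed]), collapse = ", "),
         call. = FALSE)
  }

  gen_map <- character()
  if (!is.null(generations)) {
    if (is.data.frame(generations)) {
      gen_map <- stats::setNames(as.character(generations$generation),
                                 generations$canonical)
    } else {
      gen_map <- generations
    }
    bad <- setdiff(unique(gen_map), c("1st", "2nd", "3rd", "4th", "unknown"))
    if (length(bad) > 0) {
      stop("invalid generation value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  label_map <- list()
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    stopifnot(all(c("canonical", "adr") %in% names(labels)))
    label_map <- split(labels$adr, labels$canonical)
  }

  structure(
    list(synonym_map = map, generation_map = gen_map,
         label_adr_map = label_map),
    class = "drug_dictionary"
  )
}

#' ADR-term dictionary
#'
#' Maps raw ADR strings onto preferred terms and each preferred term onto
#' exactly one system-organ class (SOC), in the style of the WHO Adverse
#' Reaction Terminology. As with [drug_dictionary()], the term map is made
#' idempotent on construction.
#'
#' @param terms Tibble or data.frame with columns `term`, `preferred`, and
#'   `soc` (the SOC of the preferred term).
#' @return An object of class `adr_dictionary`.
#' @export
adr_dictionary <- function(terms) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("term", "preferred", "soc") %in% names(terms)))
  terms <- dplyr::distinct(terms, .data$term, .data$preferred, .data$soc)
  conflict <- terms$term[duplicated(terms$term)]
  if (length(conflict) > 0) {
    stop("term(s) mapped to multiple preferred terms or SOCs: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  term_map <- stats::setNames(terms$preferred, terms$term)
  soc_tbl <- dplyr::distinct(terms, .data$preferred, .data$soc)
  soc_conflict <- soc_tbl$preferred[duplicated(soc_tbl$preferred)]
  if (length(soc_conflict) > 0) {
    stop("preferred term(s) assigned to multiple SOCs: ",
         paste(unique(soc_conflict), collapse = ", "), call. = FALSE)
  }
  soc_map <- stats::setNames(soc_tbl$soc, soc_tbl$preferred)
  self <- setdiff(unname(term_map), names(term_map))
  term_map <- c(term_map, stats::setNames(self, self))
  not_fixed <- unname(term_map[unname(term_map)]) != unname(term_map)
  if (any(not_fixed)) {
    stop("preferred term(s) are themselves synonyms (cycle): ",
         paste(unique(unname(term_map)[not_fixed]), collapse = ", "),
         call. = FALSE)
  }
  # preferred terms reached only via synonyms still need a SOC
  missing_soc <- setdiff(unname(term_map), names(soc_map))
  if (length(missing_soc) > 0) {
    stop("preferred term(s) without a SOC: ",
         paste(missing_soc, collapse = ", "), call. = FALSE)
  }
  structure(list(term_map = term_map, soc_map = soc_map),
            class = "adr_dictionary")
}

#' Load a dictionary from a delimited file
#'
#' Dispatches on column shape: a file with columns `synonym, canonical`
#' (plus optional `generation`) loads as a [drug_dictionary()]; a file with
#' columns `term, preferred, soc` loads as an [adr_dictionary()].
#'
#' @param path CSV file path.
#' @param labels_path Optional CSV (`canonical`, `adr`) of on-label ADR
#'   terms, attached when loading a drug dictionary.
#' @return A `drug_dictionary` or `adr_dictionary`.
#' @export
load_dictionary <- function(path, labels_path = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (all(c("synonym", "canonical") %in% names(raw))) {
    gens <- NULL
    if ("generation" %in% names(raw)) {
      gens <- dplyr::distinct(
        dplyr::filter(raw, !is.na(.data$generation)),
        canonical = .data$canonical, generation = .data$generation
      )
    }
    labels <- NULL
    if (!is.null(labels_path)) {
      labels <- readr::read_csv(labels_path, col_types = readr::cols(
        .default = readr::col_character()
      ), progress = FALSE)
    }
    drug_dictionary(raw[c("synonym", "canonical")], generations = gens,
                    labels = labels)
  } else if (all(c("term", "preferred", "soc") %in% names(raw))) {
    adr_dictionary(raw)
  } else {
    stop("unrecognised dictionary columns: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
}

#' Look up canonical drug names
#'
#' @param dict A `drug_dictionary`.
#' @param x Character vector of raw drug names.
#' @return Canonical names; entries absent from the dictionary are `NA`.
#' @export
canonical_drug <- function(dict, x) {
  unname(dict$synonym_map[x])
}

#' Look up preferred ADR terms
#'
#' @param dict An `adr_dictionary`.
#' @param x Character vector of raw ADR strings.
#' @return Preferred terms; entries absent from the dictionary are `NA`.
#' @export
preferred_term <- function(dict, x) {
  unname(dict$term_map[x])
}
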