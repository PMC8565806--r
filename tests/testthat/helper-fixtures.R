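# Small in-code fixtures shared across test files.

toy_reports <- function() {
  adr_reports(
    report_id = c("r1", "r2", "r3"),
    sex = c("male", "female", "male"),
    age_years = c(2L, 7L, NA),
    drugs = list("cefazolin", c("ceftezole", "cefuroxime"), "cefixime"),
    adr_terms = list(c("rash", "pruritus", "nausea"), c("rash", "fever"),
                     "vomiting"),
    causality = c("probable", "possible", "certain"),
    severity = c("non_serious", "serious", "non_serious"),
    outcome = c("recovered", "improved", "recovered"),
    route = c("injection", "injection", "oral"),
    report_date = as.Date(c("2015-03-01", "2016-07-12", NA))
  )
}

toy_drug_dict <- function() {
  drug_dictionary(
    tibble::tibble(
      synonym = c("Cefazolin Na", "cefazolin sodium", "头孢唑辟",
                  "ceftezole", "cefazolin"),
      canonical = c("cefazolin", "cefazolin", "ceftizoxime",
                    "ceftezole", "cefazolin")
    ),
    generations = tibble::tibble(
      canonical = c("cefazolin", "ceftizoxime", "ceftezole"),
      generation = c("1st", "3rd", "1st")
    ),
    labels = tibble::tibble(
      canonical = c("ceftezole", "ceftezole", "cefazolin"),
      adr = c("rash", "pruritus", "rash")
    )
  )
}

toy_adr_dict <- function() {
  adr_dictionary(tibble::tibble(
    term = c("skin rash", "rash", "pruritus", "itching", "nausea",
             "fever", "vomiting", "tremor"),
    preferred = c("rash", "rash", "pruritus", "pruritus", "nausea",
                  "fever", "vomiting", "tremor"),
    soc = c("skin and appendages disorders",
            "skin and appendages disorders",
            "skin and appendages disorders",
            "skin and appendages disorders",
            "gastro-intestinal system disorders",
            "body as a whole-general disorders",
            "gastro-intestinal system disorders",
            "central and peripheral nervous system disorders")
  ))
}

# Reconstruct report/event tables whose marginal counts equal the bundled
# study tables, so descriptive statistics can be recomputed through the
# package's own aggregation path.
study_reports_severity <- function() {
  fx <- study_fixture()
  dr <- fx$drug_reports
  n <- sum(dr$total)
  severity <- unlist(mapply(function(s, t) {
    c(rep("serious", s), rep("non_serious", t - s))
  }, dr$serious, dr$total, SIMPLIFY = FALSE), use.names = FALSE)
  drug <- rep(dr$drug, dr$total)
  adr_reports(
    report_id = sprintf("p%05d", seq_len(n)),
    sex = "unknown",
    drugs = as.list(drug),
    adr_terms = rep(list("rash"), n),
    severity = severity
  )
}

study_events <- function() {
  fx <- study_fixture()
  ae <- fx$adr_events
  n_events <- fx$counts[["events"]]
  other <- n_events - sum(ae$n)
  term <- c(rep(ae$adr, ae$n), rep("unspecified reaction", other))
  tibble::tibble(
    report_id = sprintf("e%05d", seq_along(term)),
    drug = "cephalosporin",
    adr = term
  )
}

study_soc_events <- function() {
  fx <- study_fixture()
  se <- fx$soc_events
  n_events <- fx$counts[["events"]]
  other <- n_events - sum(se$n)
  soc <- c(rep(se$soc, se$n), rep("other system disorders", other))
  tibble::tibble(
    report_id = sprintf("s%05d", seq_along(soc)),
    drug = "cephalosporin",
    adr = soc
  )
}

soc_identity_dict <- function(socs) {
  adr_dictionary(tibble::tibble(term = socs, preferred = socs, soc = socs))
}
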