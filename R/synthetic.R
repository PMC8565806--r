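# SOC assignment for the default ADR term catalog (WHO-ART-style labels).
DEFAULT_TERM_SOC <- c(
  "rash" = "skin and appendages disorders",
  "pruritus" = "skin and appendages disorders",
  "urticaria" = "skin and appendages disorders",
  "maculo-papular rash" = "skin and appendages disorders",
  "erythematous rash" = "skin and appendages disorders",
  "dermatitis" = "skin and appendages disorders",
  "allergic reaction" = "body as a whole-general disorders",
  "anaphylactoid reaction" = "body as a whole-general disorders",
  "fever" = "body as a whole-general disorders",
  "rigors" = "body as a whole-general disorders",
  "face oedema" = "body as a whole-general disorders",
  "vomiting" = "gastro-intestinal system disorders",
  "nausea" = "gastro-intestinal system disorders",
  "abdominal pain" = "gastro-intestinal system disorders",
  "diarrhoea" = "gastro-intestinal system disorders",
  "dyspnoea" = "respiratory system disorders",
  "coughing" = "respiratory system disorders",
  "flushing" = "autonomic nervous system disorders",
  "cyanosis" = "autonomic nervous system disorders",
  "dizziness" = "central and peripheral nervous system disorders",
  "palpitation" = "heart rate and rhythm disorders",
  "agitation" = "psychiatric disorders"
)

#' Default drug catalog for the synthetic generator
#'
#' The 37 named cephalosporins of the bundled study tables, with marginal
#' reporting probabilities proportional to their printed report counts and
#' per-drug serious-report proportions.
#'
#' @return A tibble with columns `name`, `prob`, `generation`,
#'   `serious_prob`.
#' @export
default_drug_catalog <- function() {
  dr <- study_fixture()$drug_reports
  dr <- dr[dr$drug != "unknown", , drop = FALSE]
  tibble::tibble(
    name = dr$drug,
    prob = dr$total / sum(dr$total),
    generation = dr$generation,
    serious_prob = dr$serious / dr$total
  )
}

#' Default ADR term catalog for the synthetic generator
#'
#' The high-frequency ADR terms of the bundled study tables (covering the
#' top 95% of events), with baseline probabilities proportional to their
#' printed event counts and a WHO-ART-style system-organ-class assignment
#' supplied by the package.
#'
#' @return A tibble with columns `term`, `prob`, `soc`.
#' @export
default_adr_catalog <- function() {
  ae <- study_fixture()$adr_events
  tibble::tibble(
    term = ae$adr,
    prob = ae$n / sum(ae$n),
    soc = unname(DEFAULT_TERM_SOC[ae$adr])
  )
}

# Default age distribution over 0-14 years: skewed toward newborns and
# toddlers (the 0-1 and 2-3 groups carry ~20% and ~15% of reports), then a
# gentle decline through school age.
DEFAULT_AGE_PROBS <- c(0.105, 0.093, 0.080, 0.069, 0.068, 0.066, 0.064,
                       0.062, 0.060, 0.058, 0.056, 0.054, 0.052, 0.050,
                       0.063)

#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a synthetic SRS database: its size, the drug and ADR-term
#' catalogs with their marginal probabilities, the mean number of distinct
#' ADR terms per report, implanted drug-ADR associations, and the
#' demographic/outcome/route marginals. Defaults emulate the shape of a
#' provincial pediatric cephalosporin database: ~1.3 ADR terms per report,
#' a 1.60 male-female ratio, an age distribution concentrated in ages 0-3,
#' 6.63% serious reports, >99% recovered or improved, and ~96% injection
#' administration.
#'
#' @param n_reports Number of reports to generate.
#' @param drugs Drug catalog: tibble with `name`, `prob` (marginal
#'   probabilities summing to 1), optional `generation` and
#'   `serious_prob`.
#' @param adrs ADR catalog: tibble with `term`, `prob` (baseline
#'   probabilities summing to 1), optional `soc`.
#' @param adr_per_report Target mean number of distinct ADR terms per
#'   report; terms per report follow a zero-truncated Poisson with this
#'   mean.
#' @param implants Tibble with `drug`, `adr`, `rate_ratio`: within the
#'   named drug's reports the ADR's baseline probability is multiplied by
#'   `rate_ratio` and the drug's term distribution renormalised.
#'   `rate_ratio = 1` is the null.
#' @param sex_probs Named probabilities over `male`, `female`, `unknown`.
#' @param age_probs Probabilities over ages 0-14 (length 15).
#' @param p_serious Global probability a report is serious; per-drug
#'   `serious_prob` in the drug catalog overrides it when
#'   `use_drug_serious = TRUE`.
#' @param use_drug_serious Draw severity from the drug catalog's
#'   `serious_prob` column instead of `p_serious`.
#' @param p_new Probability an ADR is "new" (not yet in the label).
#' @param causality_probs Named probabilities over the retained causality
#'   levels.
#' @param outcome_probs Named probabilities over outcome levels.
#' @param route_probs Named probabilities over route levels.
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_reports = 15000,
                             drugs = default_drug_catalog(),
                             adrs = default_adr_catalog(),
                             adr_per_report = 1.304,
                             implants = NULL,
                             sex_probs = c(male = 0.6142, female = 0.3849,
                                           unknown = 0.0009),
                             age_probs = DEFAULT_AGE_PROBS,
                             p_serious = 0.0663,
                             use_drug_serious = FALSE,
                             p_new = 0.1089,
                             causality_probs = c(certain = 0.20,
                                                 probable = 0.35,
                                                 possible = 0.45),
                             outcome_probs = c(recovered = 0.60,
                                               improved = 0.3918,
                                               sequelae = 0.002,
                                               death = 0.00025,
                                               unknown = 0.00595),
                             route_probs = c(injection = 0.9630,
                                             oral = 0.0366,
                                             other = 0.0003,
                                             unknown = 0.0001),
                             seed = 20140101) {
  drugs <- tibble::as_tibble(drugs)
  adrs <- tibble::as_tibble(adrs)
  stopifnot(all(c("name", "prob") %in% names(drugs)),
            all(c("term", "prob") %in% names(adrs)),
            n_reports >= 0, adr_per_report >= 1)
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-6) {
      stop(what, " probabilities must lie in [0,1] and sum to 1",
           call. = FALSE)
    }
  }
  check_probs(drugs$prob, "drug catalog")
  check_probs(adrs$prob, "ADR catalog")
  check_probs(sex_probs, "sex")
  check_probs(age_probs, "age")
  check_probs(causality_probs, "causality")
  check_probs(outcome_probs, "outcome")
  check_probs(route_probs, "route")
  stopifnot(length(age_probs) == 15, p_serious >= 0, p_serious <= 1)
  if (use_drug_serious && !("serious_prob" %in% names(drugs))) {
    stop("use_drug_serious requires a serious_prob column in the drug ",
         "catalog", call. = FALSE)
  }
  if (!is.null(implants)) {
    implants <- tibble::as_tibble(implants)
    stopifnot(all(c("drug", "adr", "rate_ratio") %in% names(implants)),
              all(implants$rate_ratio >= 0))
    bad_drug <- setdiff(implants$drug, drugs$name)
    bad_adr <- setdiff(implants$adr, adrs$term)
    if (length(bad_drug) > 0 || length(bad_adr) > 0) {
      stop("implants reference unknown drug(s)/term(s): ",
           paste(c(bad_drug, bad_adr), collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_reports = as.integer(n_reports), drugs = drugs, adrs = adrs,
         adr_per_report = adr_per_report, implants = implants,
         sex_probs = sex_probs, age_probs = age_probs,
         p_serious = p_serious, use_drug_serious = use_drug_serious,
         p_new = p_new, causality_probs = causality_probs,
         outcome_probs = outcome_probs, route_probs = route_probs,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Rate of the zero-truncated Poisson with a given mean > 1:
# solve lambda / (1 - exp(-lambda)) = m.
ztp_lambda <- function(m) {
  if (m <= 1) stop("zero-truncated Poisson mean must exceed 1",
                   call. = FALSE)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 interval = c(1e-8, m * 2 + 10), tol = 1e-12)$root
}

rztpois <- function(n, lambda) {
  u <- stats::runif(n, min = stats::ppois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` reports under a [synthetic_config()]: each report
#' gets one suspected drug from the drug marginals, a zero-truncated
#' Poisson number of distinct ADR terms drawn without replacement from
#' the baseline term probabilities — multiplied by the drug's implanted
#' rate ratios and renormalised — and demographics, severity, novelty,
#' outcome, and route from their configured marginals. Severity is drawn
#' independently of the drug-event combination unless per-drug serious
#' probabilities are enabled. Output is deterministic for a fixed seed;
#' the caller's RNG state is left untouched.
#'
#' @param config A [synthetic_config()] object.
#' @return An `adr_reports` tibble.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_reports
  if (n == 0) {
    return(adr_reports(character(0), character(0), integer(0),
                       drugs = list(), adr_terms = list(),
                       causality = character(0), severity = character(0),
                       novelty = character(0), outcome = character(0),
                       route = character(0),
                       report_date = as.Date(character(0)),
                       allergy_history = character(0)))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  drugs <- config$drugs
  adrs <- config$adrs
  n_terms <- nrow(adrs)
  drug_idx <- sample.int(nrow(drugs), n, replace = TRUE,
                         prob = drugs$prob)
  k <- if (config$adr_per_report > 1) {
    pmin(rztpois(n, ztp_lambda(config$adr_per_report)), n_terms)
  } else {
    rep(1L, n)
  }

  # per-drug term weights: baseline * implant rate ratios, renormalised
  weights <- matrix(adrs$prob, nrow = nrow(drugs), ncol = n_terms,
                    byrow = TRUE)
  if (!is.null(config$implants)) {
    di <- match(config$implants$drug, drugs$name)
    ti <- match(config$implants$adr, adrs$term)
    weights[cbind(di, ti)] <- weights[cbind(di, ti)] *
      config$implants$rate_ratio
    weights <- weights / rowSums(weights)
  }

  adr_list <- vector("list", n)
  single <- k == 1
  if (any(single)) {
    # single-term reports drug by drug in one weighted draw each
    for (g in unique(drug_idx[single])) {
      idx <- which(single & drug_idx == g)
      adr_list[idx] <- as.list(adrs$term[
        sample.int(n_terms, length(idx), replace = TRUE,
                   prob = weights[g, ])
      ])
    }
  }
  for (i in which(!single)) {
    adr_list[[i]] <- adrs$term[
      sample.int(n_terms, k[i], prob = weights[drug_idx[i], ])
    ]
  }

  p_ser <- if (config$use_drug_serious) {
    drugs$serious_prob[drug_idx]
  } else {
    config$p_serious
  }
  draw <- function(levels, probs) {
    levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
  }
  out <- tibble::tibble(
    report_id = sprintf("SR%07d", seq_len(n)),
    sex = draw(names(config$sex_probs), config$sex_probs),
    age_years = sample(0:14, n, replace = TRUE, prob = config$age_probs),
    drugs = as.list(drugs$name[drug_idx]),
    adr_terms = adr_list,
    causality = draw(names(config$causality_probs),
                     config$causality_probs),
    severity = ifelse(stats::runif(n) < p_ser, "serious", "non_serious"),
    novelty = ifelse(stats::runif(n) < config$p_new, "new", "known"),
    outcome = draw(names(config$outcome_probs), config$outcome_probs),
    route = draw(names(config$route_probs), config$route_probs),
    report_date = as.Date("2014-01-01") +
      sample.int(2191, n, replace = TRUE) - 1,
    allergy_history = NA_character_
  )
  validate_reports(out)
  out
}

#' Score signal recovery against the generating configuration
#'
#' Treats the configuration's implanted drug-ADR associations with
#' `rate_ratio > 1` as the true positives and every other scored
#' combination as a true negative, then computes sensitivity,
#' specificity, and the false-discovery proportion for each method and
#' for the consensus.
#'
#' @param signals Result of [mine_signals()] on data generated from
#'   `config`.
#' @param config The [synthetic_config()] that generated the data.
#' @return A list with `rates` (tibble: method, sensitivity, specificity,
#'   fdp, n_flagged) and `implant_detection` (per-implant consensus
#'   indicator). Sensitivity is `NA` under a null configuration (no
#'   implanted positives).
#' @export
evaluate_recovery <- function(signals, config) {
  stopifnot(inherits(config, "synthetic_config"))
  implants <- config$implants
  positives <- if (is.null(implants)) {
    implants <- tibble::tibble(drug = character(), adr = character(),
                               rate_ratio = numeric())
    implants
  } else {
    implants[implants$rate_ratio > 1, , drop = FALSE]
  }
  key <- function(d, a) paste(d, a, sep = "\r")
  sig_keys <- key(signals$drug, signals$adr)
  if (nrow(signals) > 0 &&
      length(intersect(signals$drug, config$drugs$name)) == 0) {
    stop("signal and configuration drug-ADR universes are disjoint",
         call. = FALSE)
  }
  is_pos <- sig_keys %in% key(positives$drug, positives$adr)
  one_method <- function(flag, method) {
    tp <- sum(flag & is_pos)
    fp <- sum(flag & !is_pos)
    tibble::tibble(
      method = method,
      sensitivity = if (nrow(positives) > 0) tp / nrow(positives)
                    else NA_real_,
      specificity = if (any(!is_pos)) sum(!flag & !is_pos) / sum(!is_pos)
                    else NA_real_,
      fdp = if (tp + fp > 0) fp / (tp + fp) else 0,
      n_flagged = tp + fp
    )
  }
  rates <- dplyr::bind_rows(
    one_method(signals$flag_ror, "ror"),
    one_method(signals$flag_prr, "prr"),
    one_method(signals$flag_mhra, "mhra"),
    one_method(signals$consensus, "consensus")
  )
  detected <- key(positives$drug, positives$adr) %in%
    sig_keys[signals$consensus]
  list(
    rates = rates,
    implant_detection = tibble::tibble(
      drug = positives$drug, adr = positives$adr,
      rate_ratio = positives$rate_ratio, detected = detected
    )
  )
}

#' Dictionaries matching the default synthetic catalogs
#'
#' Convenience constructors for a [drug_dictionary()] and
#' [adr_dictionary()] that treat the default catalogs' names as already
#' canonical, so synthetic data passes through [normalize_reports()]
#' unchanged.
#'
#' @return A list with `drug_dict` and `adr_dict`.
#' @export
default_dictionaries <- function() {
  dr <- default_drug_catalog()
  ad <- default_adr_catalog()
  list(
    drug_dict = drug_dictionary(
      tibble::tibble(synonym = dr$name, canonical = dr$name),
      generations = tibble::tibble(canonical = dr$name,
                                   generation = dr$generation)
    ),
    adr_dict = adr_dictionary(
      tibble::tibble(term = ad$term, preferred = ad$term, soc = ad$soc)
    )
  )
}

#' Benchmark configuration for signal-recovery studies
#'
#' Builds a [synthetic_config()] with `n_implants` implanted drug-ADR
#' associations chosen so each implant's expected target-cell count
#' (`a`) is at least `min_expected_a` under the given database size and
#' rate ratio. Implants are assigned greedily: drugs in descending order
#' of marginal probability each take the rarest still-unused ADR term
#' whose expected count clears the floor, so large drugs carry rare
#' terms and the commoner terms remain available for the smaller drugs.
#' This keeps every implant on a distinct term, which prevents implanted
#' drugs from inflating each other's background rates.
#'
#' @param n_reports Database size.
#' @param n_implants Number of implanted associations.
#' @param rate_ratio Implanted within-drug rate ratio.
#' @param min_expected_a Floor on the expected target-cell count.
#' @param seed Seed passed to [synthetic_config()].
#' @return A `synthetic_config` with the implant table attached.
#' @export
recovery_benchmark_config <- function(n_reports = 50000, n_implants = 20,
                                      rate_ratio = 5,
                                      min_expected_a = 12, seed = 1) {
  drugs <- default_drug_catalog()
  adrs <- default_adr_catalog()
  mean_terms <- 1.304
  drugs_desc <- drugs[order(drugs$prob, decreasing = TRUE), ]
  terms_asc <- adrs[order(adrs$prob), ]
  stopifnot(n_implants <= nrow(drugs_desc),
            n_implants <= nrow(terms_asc))
  used <- character()
  implants <- vector("list", n_implants)
  for (i in seq_len(n_implants)) {
    p_drug <- drugs_desc$prob[i]
    q <- terms_asc$prob
    # expected a under multiplicative implant with renormalisation
    exp_a <- n_reports * mean_terms * p_drug *
      (q * rate_ratio) / (1 + q * (rate_ratio - 1))
    ok <- exp_a >= min_expected_a & !(terms_asc$term %in% used)
    if (!any(ok)) {
      stop("no feasible ADR term for drug ", drugs_desc$name[i],
           "; increase n_reports or lower min_expected_a",
           call. = FALSE)
    }
    pick <- which(ok)[1]
    used <- c(used, terms_asc$term[pick])
    implants[[i]] <- tibble::tibble(drug = drugs_desc$name[i],
                                    adr = terms_asc$term[pick],
                                    rate_ratio = rate_ratio)
  }
  synthetic_config(n_reports = n_reports,
                   implants = dplyr::bind_rows(implants), seed = seed)
}
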