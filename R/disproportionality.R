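#' Fourfold (2 x 2) contingency table for one drug-event combination
#'
#' The counting basis of disproportionality analysis. For a target drug D
#' and target ADR term E over a background of N events:
#' `a` = events with D and E, `b` = D with any other ADR, `c` = E with any
#' other drug, `d` = everything else, so `a + b + c + d = N`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `fourfold` object with fields `a`, `b`, `c`, `d`, `n`.
#' @export
fourfold <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target ADR", "other ADRs")))
  print(m)
  cat("N =", x$n, "\n")
  invisible(x)
}

#' Build the fourfold table for a drug-ADR pair
#'
#' Counts the four cells for one target drug-event combination against the
#' background of all events supplied. The background is the event set the
#' pipeline was run on (by default, the included dataset); restricting or
#' widening the background changes every cell except `a`.
#'
#' @param events Event tibble (`report_id`, `drug`, `adr`) from
#'   [expand_events()].
#' @param drug Target canonical drug name.
#' @param adr Target ADR preferred term.
#' @return A [fourfold()] table with `N = nrow(events)`.
#' @export
build_fourfold <- function(events, drug, adr) {
  if (nrow(events) == 0) stop("background scope is empty", call. = FALSE)
  is_d <- events$drug == drug
  is_e <- events$adr == adr
  fourfold(sum(is_d & is_e), sum(is_d & !is_e),
           sum(!is_d & is_e), sum(!is_d & !is_e))
}

#' Signal-generation criteria
#'
#' Thresholds shared by the three disproportionality methods. The ROR and
#' PRR flag a drug-event combination when it has at least `min_a` events
#' and the lower bound of the 95% confidence interval exceeds
#' `ci_lower_threshold`; the MHRA composite requires at least `min_a`
#' events, PRR at or above `prr_threshold`, and a Yates-corrected
#' chi-square at or above `chi2_threshold`.
#'
#' @param min_a Minimum `a` cell count (default 3).
#' @param ci_lower_threshold CI lower-limit threshold (default 1).
#' @param prr_threshold PRR threshold for the MHRA rule (default 2).
#' @param chi2_threshold Chi-square threshold for the MHRA rule
#'   (default 4).
#' @param z Normal quantile for the CI (default 1.96, i.e. 95%).
#' @return A `signal_criteria` object.
#' @export
signal_criteria <- function(min_a = 3, ci_lower_threshold = 1,
                            prr_threshold = 2, chi2_threshold = 4,
                            z = 1.96) {
  stopifnot(min_a > 0, ci_lower_threshold > 0, prr_threshold > 0,
            chi2_threshold > 0, z > 0)
  structure(list(min_a = min_a, ci_lower_threshold = ci_lower_threshold,
                 prr_threshold = prr_threshold,
                 chi2_threshold = chi2_threshold, z = z),
            class = "signal_criteria")
}

# Vectorised internals. Zero cells make the log-scale variance infinite,
# so estimates are NA ("undefined") rather than corrected unless the
# caller opts into the Haldane-Anscombe +0.5 adjustment.
ror_vec <- function(a, b, c, d, z = 1.96, correction = 0) {
  a <- as.numeric(a) + correction; b <- as.numeric(b) + correction
  c <- as.numeric(c) + correction; d <- as.numeric(d) + correction
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  list(est = ror,
       lo = exp(log(ror) - z * se),
       hi = exp(log(ror) + z * se))
}

prr_vec <- function(a, b, c, d, z = 1.96, correction = 0) {
  a <- as.numeric(a) + correction; b <- as.numeric(b) + correction
  c <- as.numeric(c) + correction; d <- as.numeric(d) + correction
  ok <- a > 0 & c > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)),
               NA_real_)
  list(est = prr,
       lo = exp(log(prr) - z * se),
       hi = exp(log(prr) + z * se))
}

yates_vec <- function(a, b, c, d, denominator = c("standard",
                                                  "as_printed")) {
  denominator <- match.arg(denominator)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  dev <- pmax(0, abs(a * d - b * c) - n / 2)
  den <- switch(denominator,
    standard = (a + b) * (c + d) * (a + c) * (b + d),
    as_printed = (a + b) * (a + c) * (b + c) * (c + d)
  )
  ifelse(den > 0, n * dev^2 / den, NA_real_)
}

#' Reporting odds ratio for a fourfold table
#'
#' `ROR = ad / bc`, with a 95% confidence interval from the normal
#' approximation on the log scale:
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A table with any
#' zero cell has an undefined estimate (`NA`) and can never flag — a flag
#' requires a computable confidence interval.
#'
#' @param table A [fourfold()] table.
#' @param criteria A [signal_criteria()] object.
#' @param correction Additive cell correction; 0 (default) or 0.5 for
#'   Haldane-Anscombe.
#' @return A list with `ror`, `ci_low`, `ci_high`, `flag`.
#' @export
ror_stats <- function(table, criteria = signal_criteria(),
                      correction = 0) {
  r <- ror_vec(table$a, table$b, table$c, table$d, z = criteria$z,
               correction = correction)
  flag <- !is.na(r$lo) && table$a >= criteria$min_a &&
    r$lo > criteria$ci_lower_threshold
  list(ror = r$est, ci_low = r$lo, ci_high = r$hi, flag = isTRUE(flag))
}

#' Proportional reporting ratio for a fourfold table
#'
#' `PRR = [a / (a + b)] / [c / (c + d)]`, with the log-scale interval
#' `exp(log(PRR) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Undefined
#' (`NA`, never flagged) when `a = 0` or `c = 0`.
#'
#' @inheritParams ror_stats
#' @return A list with `prr`, `ci_low`, `ci_high`, `flag`.
#' @export
prr_stats <- function(table, criteria = signal_criteria(),
                      correction = 0) {
  r <- prr_vec(table$a, table$b, table$c, table$d, z = criteria$z,
               correction = correction)
  flag <- !is.na(r$lo) && table$a >= criteria$min_a &&
    r$lo > criteria$ci_lower_threshold
  list(prr = r$est, ci_low = r$lo, ci_high = r$hi, flag = isTRUE(flag))
}

#' Yates-corrected chi-square for a fourfold table
#'
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 /
#' [(a+b)(c+d)(a+c)(b+d)]`. The continuity term is clamped at zero so
#' near-independent tables score 0 instead of a spuriously inflated
#' statistic. The `"as_printed"` denominator variant
#' `(a+b)(a+c)(b+c)(c+d)` is provided for comparison with sources that
#' print the formula with transposed margins; the standard form is the
#' default and is what the MHRA rule uses.
#'
#' @param table A [fourfold()] table.
#' @param denominator `"standard"` or `"as_printed"`.
#' @return The corrected chi-square statistic; `NA` if a margin is zero.
#' @export
yates_chi2 <- function(table, denominator = "standard") {
  yates_vec(table$a, table$b, table$c, table$d, denominator = denominator)
}

#' MHRA composite signal criterion
#'
#' Flags a drug-event combination when `a >= min_a`, `PRR >=
#' prr_threshold`, and the Yates-corrected chi-square `>=
#' chi2_threshold`.
#'
#' @inheritParams ror_stats
#' @return Logical flag.
#' @export
mhra_flag <- function(table, criteria = signal_criteria()) {
  prr <- prr_vec(table$a, table$b, table$c, table$d, z = criteria$z)$est
  chi2 <- yates_chi2(table)
  isTRUE(!is.na(prr) && !is.na(chi2) &&
           table$a >= criteria$min_a &&
           prr >= criteria$prr_threshold &&
           chi2 >= criteria$chi2_threshold)
}

#' Mine disproportionality signals over all drug-event combinations
#'
#' Scores every distinct (drug, ADR) pair with at least one event against
#' the full event background: fourfold cell counts, ROR and PRR with 95%
#' confidence intervals, the Yates-corrected chi-square, the three
#' per-method flags, and the consensus flag (all three methods agree).
#' Pairs below `min_a` are still scored so sub-threshold combinations can
#' be inspected; they simply cannot flag.
#'
#' Results are ordered by drug, then ROR descending, then ADR, which is
#' deterministic for a given event set.
#'
#' @param events Event tibble from [expand_events()].
#' @param criteria A [signal_criteria()] object.
#' @param correction Additive cell correction for ROR/PRR (0 or 0.5).
#' @return A tibble with one row per scored pair: `drug`, `adr`, `a`,
#'   `b`, `c`, `d`, `n`, `ror`, `ror_ci_low`, `ror_ci_high`, `prr`,
#'   `prr_ci_low`, `prr_ci_high`, `chi2_yates`, `flag_ror`, `flag_prr`,
#'   `flag_mhra`, `consensus`.
#' @export
mine_signals <- function(events, criteria = signal_criteria(),
                         correction = 0) {
  empty <- tibble::tibble(
    drug = character(), adr = character(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    n = integer(),
    ror = numeric(), ror_ci_low = numeric(), ror_ci_high = numeric(),
    prr = numeric(), prr_ci_low = numeric(), prr_ci_high = numeric(),
    chi2_yates = numeric(),
    flag_ror = logical(), flag_prr = logical(), flag_mhra = logical(),
    consensus = logical()
  )
  if (nrow(events) == 0) return(empty)
  n_total <- nrow(events)
  pair <- events |>
    dplyr::count(.data$drug, .data$adr, name = "a")
  drug_tot <- events |> dplyr::count(.data$drug, name = "n_drug")
  adr_tot <- events |> dplyr::count(.data$adr, name = "n_adr")
  tab <- pair |>
    dplyr::left_join(drug_tot, by = "drug") |>
    dplyr::left_join(adr_tot, by = "adr") |>
    dplyr::mutate(
      b = .data$n_drug - .data$a,
      c = .data$n_adr - .data$a,
      d = n_total - .data$n_drug - .data$n_adr + .data$a,
      n = n_total
    )
  ror_r <- ror_vec(tab$a, tab$b, tab$c, tab$d, z = criteria$z,
                   correction = correction)
  prr_r <- prr_vec(tab$a, tab$b, tab$c, tab$d, z = criteria$z,
                   correction = correction)
  chi2 <- yates_vec(tab$a, tab$b, tab$c, tab$d)
  min_a_ok <- tab$a >= criteria$min_a
  flag_ror <- !is.na(ror_r$lo) & min_a_ok &
    ror_r$lo > criteria$ci_lower_threshold
  flag_prr <- !is.na(prr_r$lo) & min_a_ok &
    prr_r$lo > criteria$ci_lower_threshold
  flag_mhra <- !is.na(prr_r$est) & !is.na(chi2) & min_a_ok &
    prr_r$est >= criteria$prr_threshold & chi2 >= criteria$chi2_threshold
  out <- tibble::tibble(
    drug = tab$drug, adr = tab$adr,
    a = as.integer(tab$a), b = as.integer(tab$b),
    c = as.integer(tab$c), d = as.integer(tab$d),
    n = as.integer(tab$n),
    ror = ror_r$est, ror_ci_low = ror_r$lo, ror_ci_high = ror_r$hi,
    prr = prr_r$est, prr_ci_low = prr_r$lo, prr_ci_high = prr_r$hi,
    chi2_yates = chi2,
    flag_ror = flag_ror, flag_prr = flag_prr, flag_mhra = flag_mhra,
    consensus = flag_ror & flag_prr & flag_mhra
  )
  dplyr::arrange(out, .data$drug, dplyr::desc(.data$ror), .data$adr)
}

#' Flag off-label ADR signals
#'
#' Marks each scored drug-event combination as off-label when the ADR
#' term is absent from the drug's on-label term set. Drugs without label
#' data in the dictionary get `NA` (unknown label status) rather than a
#' guess.
#'
#' @param signals Result of [mine_signals()].
#' @param drug_dict A [drug_dictionary()] whose `label_adr_map` holds the
#'   on-label ADR preferred terms per canonical drug name.
#' @return `signals` with a logical `off_label` column (`NA` = unknown).
#' @export
off_label_flags <- function(signals, drug_dict) {
  label_map <- drug_dict$label_adr_map
  signals$off_label <- mapply(function(drug, adr) {
    terms <- label_map[[drug]]
    if (is.null(terms)) NA else !(adr %in% terms)
  }, signals$drug, signals$adr, USE.NAMES = FALSE)
  signals
}
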