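# Independent oracle implementations used to cross-check the package's
# disproportionality statistics. These deliberately take different
# computational routes (log-space arithmetic, chisq.test, explicit
# expected-count loops) from the implementation under test.

oracle_ror <- function(a, b, c, d, z = 1.96) {
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = exp(log_or), lo = exp(log_or - z * se),
    hi = exp(log_or + z * se))
}

oracle_prr <- function(a, b, c, d, z = 1.96) {
  log_prr <- log(a) - log(a + b) - log(c) + log(c + d)
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  c(est = exp(log_prr), lo = exp(log_prr - z * se),
    hi = exp(log_prr + z * se))
}

# Yates-corrected 2x2 chi-square via R's own test implementation.
oracle_yates <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), 2, 2)
  unname(suppressWarnings(stats::chisq.test(m, correct = TRUE))$statistic)
}

# Pearson statistic from first principles: explicit expected counts.
oracle_pearson <- function(m) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      stat <- stat + (m[i, j] - e)^2 / e
    }
  }
  stat
}

# Random fourfold tables with strictly positive cells.
random_tables <- function(n, max_cell = 500) {
  tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE),
    b = sample.int(max_cell, n, replace = TRUE),
    c = sample.int(max_cell, n, replace = TRUE),
    d = sample.int(max_cell, n, replace = TRUE)
  )
}

# Brute-force event recount for fourfold construction.
oracle_fourfold <- function(events, drug, adr) {
  a <- b <- c <- d <- 0L
  for (i in seq_len(nrow(events))) {
    di <- events$drug[i] == drug
    ei <- events$adr[i] == adr
    if (di && ei) a <- a + 1L
    else if (di) b <- b + 1L
    else if (ei) c <- c + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = c, d = d)
}
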