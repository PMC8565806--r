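test_that("frequency tables honour their denominator and rounding", {
  ft <- frequency_table(c("a", "b", "c"), c(50, 30, 20))
  expect_equal(ft$percent, c(50, 30, 20))
  expect_equal(ft$cumulative_percent, c(50, 80, 100))
  expect_equal(attr(ft, "denominator"), 100L)
  # non-exhaustive labels keep the explicit denominator
  ft2 <- frequency_table("a", 25, denominator = 200)
  expect_equal(ft2$percent, 12.5)
  expect_error(frequency_table("a", 10, denominator = 5))
  # half-up rounding at the second decimal
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(1.605, 2), 1.61)
})

test_that("exhaustive frequency tables sum to the denominator", {
  withr::with_seed(5, {
    for (i in 1:20) {
      k <- sample(2:8, 1)
      counts <- sample(1:500, k)
      ft <- frequency_table(paste0("l", 1:k), counts)
      expect_equal(sum(ft$count), attr(ft, "denominator"))
      expect_lte(abs(sum(ft$percent) - 100), 0.01 * k)
      expect_true(all(diff(ft$cumulative_percent) >= 0))
    }
  })
})

test_that("sex summary computes the male-female ratio", {
  reports <- adr_reports(
    report_id = as.character(1:20),
    sex = c(rep("male", 10), rep("female", 10)),
    drugs = rep(list("d"), 20), adr_terms = rep(list("e"), 20)
  )
  s <- sex_summary(reports)
  expect_equal(s$ratio, 1.00)
  no_f <- adr_reports(as.character(1:5), sex = rep("male", 5),
                      drugs = rep(list("d"), 5),
                      adr_terms = rep(list("e"), 5))
  s2 <- sex_summary(no_f)
  expect_false(s2$ratio_defined)
  expect_true(is.na(s2$ratio))
})

test_that("severity summary partitions totals and tracks novelty", {
  reports <- adr_reports(
    report_id = as.character(1:10),
    drugs = rep(list("d"), 10), adr_terms = rep(list("e"), 10),
    severity = c(rep("serious", 10)),
    novelty = c(rep("new", 3), rep("known", 7))
  )
  s <- severity_summary(reports)
  expect_equal(s$n_serious + s$n_non_serious, s$n_total)
  expect_equal(s$percent_serious, 100.00)
  expect_equal(s$n_new_serious, 3)
})

test_that("stratified severity aggregates to the overall summary", {
  cfg <- synthetic_config(n_reports = 2000, seed = 99,
                          use_drug_serious = TRUE)
  reports <- generate_reports(cfg)
  total <- severity_summary(reports)
  for (strat in c("sex", "age_group", "drug")) {
    tab <- severity_by_stratum(reports, strat)
    expect_equal(sum(tab$n_serious), total$n_serious)
    expect_equal(sum(tab$n_total), total$n_total)
  }
  # single-report stratum edge case
  one <- adr_reports("r", drugs = list("solo"), adr_terms = list("e"),
                     severity = "serious")
  tab1 <- severity_by_stratum(one, "drug")
  expect_equal(tab1$percent_serious, 100.00)
})

test_that("pearson chi-square matches a first-principles oracle", {
  # hand-computed 2x2: chi2 = 60 * (20*20 - 10*10)^2 / 30^4 = 20/3
  res <- pearson_chi2(matrix(c(20, 10, 10, 20), 2, 2), yates = FALSE)
  expect_equal(res$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # independence gives exactly zero
  expect_equal(pearson_chi2(matrix(10, 2, 2))$chi2, 0)
  # the continuity correction shrinks the statistic
  corrected <- pearson_chi2(matrix(c(20, 10, 10, 20), 2, 2), yates = TRUE)
  expect_lt(corrected$chi2, res$chi2)
  withr::with_seed(17, {
    for (i in 1:200) {
      r <- sample(2:4, 1); k <- sample(2:4, 1)
      m <- matrix(sample(1:200, r * k, replace = TRUE), r, k)
      got <- pearson_chi2(m)
      expect_equal(got$chi2, oracle_pearson(m), tolerance = 1e-9)
      expect_equal(got$df, (r - 1) * (k - 1))
      expect_equal(got$p, stats::pchisq(got$chi2, got$df,
                                        lower.tail = FALSE))
    }
  })
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, 2)),
               "degenerate margin")
})

test_that("ADR frequencies bucket unmapped terms as unclassified", {
  events <- tibble::tibble(
    report_id = as.character(1:4), drug = "d",
    adr = c("rash", "rash", "nausea", "mystery term")
  )
  ft <- adr_frequency(events, toy_adr_dict(), level = "soc")
  expect_true("unclassified" %in% ft$label)
  expect_equal(attr(ft, "denominator"), 4L)
  term_ft <- adr_frequency(events, level = "term")
  expect_equal(term_ft$count[term_ft$label == "rash"], 2L)
})

test_that("outcome summary extracts death cases", {
  reports <- adr_reports(
    report_id = as.character(1:100),
    sex = c("female", rep("male", 99)),
    drugs = rep(list("d"), 100), adr_terms = rep(list("e"), 100),
    outcome = c("death", rep("improved", 99))
  )
  out <- outcome_summary(reports)
  expect_equal(out$percent_recovered_or_improved, 99.00)
  expect_equal(nrow(out$deaths), 1)
  expect_equal(out$deaths$sex, "female")
  none <- outcome_summary(toy_reports())
  expect_equal(nrow(none$deaths), 0)
})

test_that("route summary covers a single-route set", {
  reports <- adr_reports(as.character(1:7), drugs = rep(list("d"), 7),
                         adr_terms = rep(list("e"), 7),
                         route = rep("oral", 7))
  ft <- route_summary(reports)
  expect_equal(ft$label, "oral")
  expect_equal(ft$percent, 100.00)
})
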