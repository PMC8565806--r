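test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_reports = 500, seed = 42)
  r1 <- generate_reports(cfg)
  r2 <- generate_reports(cfg)
  expect_identical(r1, r2)
  r3 <- generate_reports(synthetic_config(n_reports = 500, seed = 43))
  expect_false(identical(r1, r3))
  expect_equal(nrow(generate_reports(
    synthetic_config(n_reports = 0, seed = 1))), 0)
})

test_that("degenerate single-drug single-ADR config collapses to one
           event type", {
  cfg <- synthetic_config(
    n_reports = 50,
    drugs = tibble::tibble(name = "onlydrug", prob = 1),
    adrs = tibble::tibble(term = "onlyadr", prob = 1,
                          soc = "general disorders"),
    adr_per_report = 1, seed = 9
  )
  events <- expand_events(generate_reports(cfg))
  expect_equal(nrow(events), 50)
  expect_equal(unique(events$drug), "onlydrug")
  expect_equal(unique(events$adr), "onlyadr")
})

test_that("configured marginals are recovered at scale", {
  cfg <- synthetic_config(n_reports = 20000, seed = 77)
  reports <- generate_reports(cfg)
  # sex ratio near the configured 1.60
  s <- sex_summary(reports)
  expect_equal(s$n_male / s$n_female, 1.60, tolerance = 0.05)
  # serious fraction near the configured 6.63%
  expect_equal(severity_summary(reports)$percent_serious, 6.63,
               tolerance = 0.15)
  # drug marginals proportional to the catalog
  drug_counts <- table(unlist(reports$drugs))
  top <- names(sort(drug_counts, decreasing = TRUE))[1]
  expect_equal(top, cfg$drugs$name[which.max(cfg$drugs$prob)])
  # ages concentrated in the youngest groups
  expect_gt(mean(reports$age_years <= 3), 0.30)
})

test_that("an implanted rate ratio is reproduced empirically", {
  # small baseline keeps the renormalisation distortion below the
  # Monte-Carlo tolerance
  cfg <- synthetic_config(
    n_reports = 50000, seed = 1234,
    implants = tibble::tibble(drug = "ceftezole", adr = "agitation",
                              rate_ratio = 10)
  )
  events <- expand_events(generate_reports(cfg))
  tab <- build_fourfold(events, "ceftezole", "agitation")
  observed_rr <- (tab$a / (tab$a + tab$b)) / (tab$c / (tab$c + tab$d))
  expect_equal(observed_rr, 10, tolerance = 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(drugs = tibble::tibble(
    name = c("a", "b"), prob = c(0.6, 0.6))), "sum to 1")
  expect_error(synthetic_config(implants = tibble::tibble(
    drug = "not-a-drug", adr = "rash", rate_ratio = 2)), "unknown")
  expect_error(synthetic_config(sex_probs = c(male = 1.5,
                                              female = -0.5)),
               "sum to 1|\\[0,1\\]")
})

test_that("recovery evaluation scores implants against mined flags", {
  implants <- tibble::tibble(drug = c("ceftezole", "cefuroxime"),
                             adr = c("dizziness", "palpitation"),
                             rate_ratio = c(12, 12))
  cfg <- synthetic_config(n_reports = 30000, seed = 555,
                          implants = implants)
  signals <- mine_signals(expand_events(generate_reports(cfg)))
  rec <- evaluate_recovery(signals, cfg)
  expect_equal(rec$rates$method, c("ror", "prr", "mhra", "consensus"))
  expect_true(all(rec$rates$sensitivity >= 0 &
                    rec$rates$sensitivity <= 1))
  cons <- rec$rates[rec$rates$method == "consensus", ]
  expect_equal(cons$sensitivity, 1)
  expect_true(all(rec$implant_detection$detected))
  # consensus flags no more than any single method
  expect_true(all(cons$n_flagged <= rec$rates$n_flagged))
})

test_that("a null configuration reports sensitivity as not applicable", {
  cfg <- synthetic_config(n_reports = 3000, seed = 31)
  signals <- mine_signals(expand_events(generate_reports(cfg)))
  rec <- evaluate_recovery(signals, cfg)
  expect_true(all(is.na(rec$rates$sensitivity)))
  expect_equal(nrow(rec$implant_detection), 0)
})

test_that("consensus sensitivity rises with rate ratio and sample size", {
  sens <- function(n, rr, seed) {
    implants <- tibble::tibble(drug = c("ceftezole", "ceftazidime"),
                               adr = c("dizziness", "rigors"),
                               rate_ratio = rr)
    cfg <- synthetic_config(n_reports = n, seed = seed,
                            implants = implants)
    rec <- evaluate_recovery(
      mine_signals(expand_events(generate_reports(cfg))), cfg)
    rec$rates$sensitivity[rec$rates$method == "consensus"]
  }
  expect_lte(sens(20000, 1.2, 8), sens(20000, 6, 8))
  expect_lte(sens(1500, 6, 9), sens(30000, 6, 9))
})

test_that("bundled study tables load with their printed totals", {
  fx <- study_fixture()
  expect_equal(sum(fx$drug_reports$total),
               unname(fx$counts["included_reports"]))
  expect_equal(fx$drug_reports$total[
    fx$drug_reports$drug == "ceftezole"], 2325)
  # 18 third-generation products listed
  expect_equal(sum(fx$drug_reports$generation == "3rd"), 18)
  expect_equal(nrow(fx$deaths), 4)
  expect_equal(sum(fx$deaths$sex == "male"), 2)
  expect_lte(sum(fx$soc_events$n), unname(fx$counts["events"]))
  # default catalogs are valid probability vectors over the fixtures
  expect_equal(sum(default_drug_catalog()$prob), 1)
  expect_equal(sum(default_adr_catalog()$prob), 1)
  expect_false(any(is.na(default_adr_catalog()$soc)))
})
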