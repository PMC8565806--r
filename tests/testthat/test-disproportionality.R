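test_that("fourfold construction matches a brute-force recount", {
  events <- tibble::tibble(
    report_id = as.character(1:10),
    drug = c(rep("D1", 5), rep("D2", 5)),
    adr = c("rash", "rash", "rash", "fever", "nausea",
            "rash", "fever", "fever", "nausea", "nausea")
  )
  tab <- build_fourfold(events, "D1", "rash")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(3, 2, 1, 4))
  expect_equal(tab$n, 10)
  # drug absent from the universe
  tab0 <- build_fourfold(events, "D9", "rash")
  expect_equal(c(tab0$a, tab0$b), c(0, 0))
  expect_error(build_fourfold(events[0, ], "D1", "rash"), "empty")
  withr::with_seed(23, {
    for (i in 1:25) {
      ev <- tibble::tibble(
        report_id = as.character(1:40),
        drug = sample(paste0("D", 1:4), 40, replace = TRUE),
        adr = sample(paste0("E", 1:5), 40, replace = TRUE)
      )
      d <- sample(paste0("D", 1:4), 1); e <- sample(paste0("E", 1:5), 1)
      tt <- build_fourfold(ev, d, e)
      expect_equal(c(a = tt$a, b = tt$b, c = tt$c, d = tt$d),
                   oracle_fourfold(ev, d, e))
      expect_equal(tt$a + tt$b + tt$c + tt$d, tt$n)
    }
  })
})

test_that("ROR and PRR match frozen hand computations", {
  tab <- fourfold(10, 90, 100, 9900)
  r <- ror_stats(tab)
  expect_equal(r$ror, 11.00, tolerance = 1e-12)
  expect_equal(r$ci_low, 5.56, tolerance = 1e-3)
  expect_true(r$flag)
  p <- prr_stats(tab)
  expect_equal(p$prr, 10.00, tolerance = 1e-12)
  expect_equal(p$ci_low, 5.38, tolerance = 1e-3)
  expect_true(p$flag)
  expect_equal(yates_chi2(tab), 66.33, tolerance = 1e-3)
  expect_true(mhra_flag(tab))
})

test_that("balanced and proportional tables are not signals", {
  flat <- fourfold(5, 5, 5, 5)
  expect_equal(ror_stats(flat)$ror, 1)
  expect_false(ror_stats(flat)$flag)
  expect_false(mhra_flag(flat))
  # proportional rows: PRR exactly 1
  prop <- fourfold(10, 90, 20, 180)
  expect_equal(prr_stats(prop)$prr, 1)
  expect_false(prr_stats(prop)$flag)
})

test_that("zero cells yield undefined estimates that never flag", {
  tab <- fourfold(12, 0, 7, 100)
  r <- ror_stats(tab)
  expect_true(is.na(r$ror))
  expect_false(r$flag)
  # the Haldane-Anscombe option makes the estimate computable
  r5 <- ror_stats(tab, correction = 0.5)
  expect_false(is.na(r5$ror))
  p <- prr_stats(fourfold(0, 10, 5, 100))
  expect_true(is.na(p$prr))
  expect_false(p$flag)
})

test_that("the count gate blocks small-a tables regardless of effect", {
  huge <- fourfold(2, 1, 1, 10000)
  expect_false(ror_stats(huge)$flag)
  expect_false(prr_stats(huge)$flag)
  expect_false(mhra_flag(huge))
})

test_that("yates chi-square clamps near-independent tables to zero", {
  # |ad - bc| = |36 - 35| = 1 < N/2
  tab <- fourfold(6, 5, 7, 6)
  expect_equal(yates_chi2(tab), 0)
})

test_that("yates chi-square is symmetric under row swap", {
  withr::with_seed(31, {
    tabs <- random_tables(1000, max_cell = 300)
    chi_ab <- mapply(function(a, b, c, d) yates_chi2(fourfold(a, b, c, d)),
                     tabs$a, tabs$b, tabs$c, tabs$d)
    chi_ba <- mapply(function(a, b, c, d) yates_chi2(fourfold(c, d, a, b)),
                     tabs$a, tabs$b, tabs$c, tabs$d)
    expect_equal(chi_ab, chi_ba, tolerance = 1e-12)
  })
})

test_that("the printed-denominator chi-square variant is available", {
  tab <- fourfold(10, 90, 100, 9900)
  std <- yates_chi2(tab)
  alt <- yates_chi2(tab, denominator = "as_printed")
  expect_false(isTRUE(all.equal(std, alt)))
  n <- tab$n
  dev <- (abs(10 * 9900 - 90 * 100) - n / 2)^2
  expect_equal(alt, n * dev / (100 * 110 * 190 * 10000),
               tolerance = 1e-12)
})

test_that("mining scores every pair, orders deterministically, and keeps
           consensus inside each method set", {
  cfg <- synthetic_config(
    n_reports = 6000, seed = 404,
    implants = tibble::tibble(drug = c("ceftezole", "ceftazidime"),
                              adr = c("dizziness", "palpitation"),
                              rate_ratio = c(8, 8))
  )
  events <- expand_events(generate_reports(cfg))
  signals <- mine_signals(events)
  # universe: every observed pair once
  expect_equal(nrow(signals),
               nrow(dplyr::distinct(events, drug, adr)))
  expect_true(all(signals$a >= 1))
  expect_equal(signals$consensus,
               signals$flag_ror & signals$flag_prr & signals$flag_mhra)
  expect_true(all(signals$consensus <= signals$flag_ror))
  expect_true(all(signals$consensus <= signals$flag_prr))
  expect_true(all(signals$consensus <= signals$flag_mhra))
  # margins are consistent with the event universe
  expect_true(all(signals$a + signals$b + signals$c + signals$d ==
                    nrow(events)))
  # implanted associations surface as consensus signals
  implanted <- dplyr::semi_join(signals, cfg$implants,
                                by = c("drug", "adr"))
  expect_true(all(implanted$consensus))
  # deterministic ordering
  expect_equal(signals, mine_signals(events[sample(nrow(events)), ]))
  expect_equal(nrow(mine_signals(events[0, ])), 0)
})

test_that("CIs bracket their point estimates when defined", {
  withr::with_seed(47, {
    tabs <- random_tables(500, max_cell = 200)
    for (i in seq_len(50)) {
      tab <- fourfold(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
      r <- ror_stats(tab); p <- prr_stats(tab)
      expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
      expect_true(p$ci_low <= p$prr && p$prr <= p$ci_high)
    }
  })
})

test_that("off-label flagging distinguishes labelled, unlabelled, and
           unknown-label drugs", {
  signals <- tibble::tibble(
    drug = c("ceftezole", "ceftezole", "mysterycillin"),
    adr = c("tremor", "rash", "rash")
  )
  flagged <- off_label_flags(signals, toy_drug_dict())
  expect_equal(flagged$off_label, c(TRUE, FALSE, NA))
})

test_that("statistics are monotone in the target cell", {
  # raising a with b, c, d fixed strengthens every statistic; the
  # chi-square claim is restricted to positively associated tables,
  # where moving a away from independence increases the deviation
  grid <- expand.grid(b = c(2, 6, 11), c = c(2, 6, 11), d = c(3, 9, 12))
  for (i in seq_len(nrow(grid))) {
    b <- grid$b[i]; c <- grid$c[i]; d <- grid$d[i]
    a_vals <- 1:12
    res <- t(vapply(a_vals, function(a) {
      tab <- fourfold(a, b, c, d)
      c(ror_stats(tab)$ror, prr_stats(tab)$prr, yates_chi2(tab))
    }, numeric(3)))
    expect_true(all(diff(res[, 1]) >= 0))
    expect_true(all(diff(res[, 2]) >= 0))
    pos <- a_vals * d - b * c >= 0
    if (sum(pos) > 1) {
      expect_true(all(diff(res[pos, 3]) >= -1e-12))
    }
  }
})
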