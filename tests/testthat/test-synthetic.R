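test_that("ledger generation is deterministic given the seed", {
  spec <- generator_spec()
  a <- generate_ledger(spec, seed = 123)
  b <- generate_ledger(spec, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_ledger(spec, seed = 124)
  expect_false(identical(a$amount, c$amount))
})

test_that("generated ledgers hit the share targets and validate", {
  spec <- generator_spec(personnel_share = 0.75)
  led <- generate_ledger(spec, seed = 42)
  expect_equal(nrow(validate_ledger(led)), 0)
  v <- value_ledger(led, generic_wage_table(), default_macro_table())
  s <- summarize_ledger(v, "vietnam", "inddex24", spec$n_respondents)
  pers_share <- s$time_cost / s$total
  expect_gt(pers_share, 0.67)
  expect_lt(pers_share, 0.83)
  shares <- s$by_activity$cost_usd / s$total
  names(shares) <- s$by_activity$activity
  for (a in cost_activities) {
    expect_lt(abs(shares[[a]] - spec$activity_shares[[a]]), 0.02)
  }
  # capital items present with lives from the standard set
  cap <- led[led$is_capital, ]
  expect_gt(nrow(cap), 0)
  expect_true(all(cap$useful_life_years %in% c(2, 3, 4, 10)))
  expect_setequal(unique(led$modality), c("inddex24", "papi", "shared"))
})

test_that("generator specs reject infeasible inputs", {
  expect_error(generator_spec(n_respondents = 0), "positive")
  expect_error(generator_spec(activity_shares = c(training = 1)), "enum")
  sh <- c(dietary_reference_data_prep = 0.5, survey_preparation = 0.5,
          training = 0.5, survey_execution = 0, data_entry = 0,
          data_cleaning_processing = 0, administration = 0)
  expect_error(generator_spec(activity_shares = sh), "sum to 1")
})

test_that("the calibrated study fixture reproduces the published cost surface", {
  for (ctry in c("vietnam", "burkina_faso")) {
    fx <- study_fixture(ctry)
    expect_equal(nrow(validate_ledger(fx$ledger, fx$macro)), 0)
    v <- value_ledger(fx$ledger, fx$wages, fx$macro)
    for (arm in c("inddex24", "papi")) {
      s <- summarize_ledger(v, ctry, arm, fx$n[[arm]])
      expect_equal(s$total, fx$totals[[arm]], tolerance = 1e-6)
    }
    # re-running the generator gives the identical ledger
    fx2 <- study_fixture(ctry)
    expect_identical(as.data.frame(fx$ledger), as.data.frame(fx2$ledger))
  }
  # reference-data preparation share: about 37 % (inddex24) / 34 % (papi) in
  # Viet Nam, within one percentage point
  fx <- study_fixture("vietnam")
  v <- value_ledger(fx$ledger, fx$wages, fx$macro)
  s_in <- summarize_ledger(v, "vietnam", "inddex24", 147)
  sh <- share_report(s_in)
  ref <- sh$share[sh$level == "dietary_reference_data_prep"]
  expect_lt(abs(ref - 0.37), 0.01)
  s_pa <- summarize_ledger(v, "vietnam", "papi", 147)
  sh_pa <- share_report(s_pa)
  expect_lt(abs(sh_pa$share[sh_pa$level == "dietary_reference_data_prep"] -
                  0.34), 0.01)
})

test_that("timing generation respects modality rules and boundary sizes", {
  tm <- generate_timings(2, seed = 8)
  segs <- c("pass1", "pass2", "pass3", "nonstd_recipe", "pass4")
  expect_true(all(as.matrix(tm[, segs]) >= 0))
  expect_true(all(is.na(tm$menu[tm$modality == "papi"])))
  expect_true(all(!is.na(tm$menu[tm$modality == "inddex24"])))
  expect_true(all(tm$total > 0))
  # totals are exact segment sums by construction
  sums <- rowSums(as.matrix(tm[, c(segs, "menu")]), na.rm = TRUE)
  expect_equal(sums, tm$total, tolerance = 1e-9)
})

test_that("large samples concentrate near the generator mean", {
  tm <- generate_timings(1000, seed = 20)
  m <- mean(tm$total[tm$modality == "inddex24"])
  expect_lt(abs(m - 39), 1)
})

test_that("timing summaries recover generator parameters across seeds", {
  for (seed in c(101, 202, 303)) {
    tm <- generate_timings(400, seed = seed,
                           total_mean = c(inddex24 = 39, papi = 44),
                           total_sd = c(inddex24 = 15, papi = 10))
    s <- summarize_timings(tm)
    for (arm in c("inddex24", "papi")) {
      mu <- c(inddex24 = 39, papi = 44)[[arm]]
      sd <- c(inddex24 = 15, papi = 10)[[arm]]
      row <- s[s$modality == arm & s$segment == "total", ]
      # 3-sigma Monte-Carlo bounds plus a small truncation allowance
      expect_lt(abs(row$mean - mu), 3 * sd / sqrt(400) + 0.35)
      expect_lt(abs(row$sd - sd), 3 * sd / sqrt(2 * 399) + 0.35)
    }
    # segment additivity: mean(total) equals the sum of segment means
    tot <- s[s$segment == "total", ]
    seg_sum <- tapply(
      s$mean[!(s$segment %in% "total")],
      s$modality[!(s$segment %in% "total")], sum
    )
    expect_equal(as.numeric(seg_sum[tot$modality]), tot$mean,
                 tolerance = 1e-9)
  }
})

test_that("lognormal totals are available by flag", {
  tm <- generate_timings(500, seed = 31, family = "lognormal")
  expect_true(all(tm$total > 0))
  m <- mean(tm$total[tm$modality == "papi"])
  expect_lt(abs(m - 44), 2)
})
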