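test_that("summarize_ledger satisfies its conservation invariants", {
  fx <- study_fixture("vietnam")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  for (arm in c("inddex24", "papi")) {
    s <- summarize_ledger(valued, "vietnam", arm, fx$n[[arm]])
    expect_equal(sum(s$by_activity$cost_usd), s$total, tolerance = 1e-9)
    expect_equal(sum(s$by_centre$cost_usd), s$total, tolerance = 1e-9)
    expect_equal(s$time_cost + s$nontime_cost, s$total, tolerance = 1e-9)
    expect_equal(s$per_respondent, s$total / s$n_respondents)
  }
})

test_that("an empty arm slice yields a zero summary with a warning", {
  valued <- value_ledger(toy_ledger(), toy_wages(), toy_macro())
  expect_warning(
    s <- summarize_ledger(valued, "burkina_faso", "papi", 10),
    "no items"
  )
  expect_equal(s$total, 0)
  expect_equal(s$per_respondent, 0)
})

test_that("per-respondent arithmetic and rounding follow the reporting rule", {
  led <- cost_ledger(data.frame(
    country = "vietnam", modality = "inddex24", activity = "training",
    cost_centre = "supplies", currency = "USD", year = 2019, amount = 147
  ))
  v <- value_ledger(led, toy_wages(), toy_macro())
  s <- summarize_ledger(v, "vietnam", "inddex24", 147)
  expect_equal(s$per_respondent, 1)
  expect_equal(cost_per_respondent(120483, 147), 820)
  expect_equal(cost_per_respondent(78105, 145), 539)
  expect_equal(cost_per_respondent(0, 147), 0)
  expect_error(cost_per_respondent(100, 0), "positive")
})

test_that("summarize_ledger matches a brute-force loop on random ledgers", {
  for (seed in 1:5) {
    spec <- generator_spec(n_items_per_activity = 3, total_cost = 5e4)
    led <- generate_ledger(spec, seed = seed)
    led <- led[sample(nrow(led), min(50, nrow(led))), ]
    v <- value_ledger(cost_ledger(led), generic_wage_table(), toy_macro())
    for (arm in c("inddex24", "papi")) {
      s <- summarize_ledger(v, "vietnam", arm, 100)
      expect_equal(s$total, brute_force_total(v, "vietnam", arm),
                   tolerance = 1e-9)
    }
  }
})

test_that("adding a positive-cost item never decreases total or per-respondent", {
  fx <- study_fixture("burkina_faso")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  s0 <- summarize_ledger(valued, "burkina_faso", "papi", 146)
  extra <- valued[1, ]
  extra$id <- "extra"
  extra$modality <- "papi"
  extra$cost_usd <- 500
  s1 <- summarize_ledger(dplyr::bind_rows(valued, extra), "burkina_faso",
                         "papi", 146)
  expect_gt(s1$total, s0$total)
  expect_gt(s1$per_respondent, s0$per_respondent)
})

test_that("arm differences use unrounded per-respondent values", {
  fx <- study_fixture("vietnam")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  a <- summarize_ledger(valued, "vietnam", "inddex24", 147)
  b <- summarize_ledger(valued, "vietnam", "papi", 147)
  d <- arm_difference(a, b)
  # 755.13 - 819.61 = -64.48 -> -64, not round(755) - round(820) = -65
  expect_equal(d$per_respondent, -64)
  expect_equal(d$total, a$total - b$total)
  dd <- arm_difference(a, a)
  expect_equal(dd$per_respondent, 0)
  expect_true(all(dd$by_activity$difference == 0))
  c_wrong <- summarize_ledger(valued, "vietnam", "papi", 147)
  c_wrong$country <- "burkina_faso"
  expect_error(arm_difference(a, c_wrong), "different countries")
})

test_that("share_report returns unit-sum shares per axis", {
  fx <- study_fixture("vietnam")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  s <- summarize_ledger(valued, "vietnam", "inddex24", 147)
  sh <- share_report(s)
  sums <- tapply(sh$share, sh$axis, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  # degenerate single-activity ledger
  v1 <- value_ledger(toy_ledger()[3, ], toy_wages(), toy_macro())
  s1 <- summarize_ledger(v1, "vietnam", "papi", 10)
  sh1 <- share_report(s1)
  expect_equal(sh1$share[sh1$level == "training"], 1)
  # forced arithmetic: personnel 75 / other 25
  led <- cost_ledger(tibble::tibble(
    country = "vietnam", modality = c("inddex24", "inddex24"),
    activity = "administration", cost_centre = c("personnel", "other"),
    currency = "USD", year = 2019L, amount = c(0, 25),
    role = c("enumerator", NA), person_minutes = c(450, NA)
  ))
  v <- value_ledger(led, toy_wages(), toy_macro())
  s2 <- summarize_ledger(v, "vietnam", "inddex24", 10)
  sh2 <- share_report(s2)
  expect_equal(sh2$share[sh2$level == "personnel"], 0.75)
})

test_that("tidy and glance expose the summary as tibbles", {
  fx <- study_fixture("vietnam")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  s <- summarize_ledger(valued, "vietnam", "inddex24", 147)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$axis), c("activity", "cost_centre"))
  gl <- glance(s)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total, s$total)
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})

test_that("the cost report carries activity rows plus total and efficiency rows", {
  fx <- study_fixture("burkina_faso")
  res <- run_primary_analysis(fx$ledger, fx$wages, fx$macro, fx$n,
                              "burkina_faso")
  rep <- res$report
  expect_equal(nrow(rep), length(cost_activities) + 2)
  expect_equal(rep$inddex24[rep$row == "total"], 78105)
  expect_equal(rep$papi[rep$row == "per_respondent"], 544)
})
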