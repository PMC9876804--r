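usd <- function(amount, year = 2019L) {
  data.frame(amount = amount, currency = "USD", year = as.integer(year))
}

test_that("deflate applies the deflator ratio of the item's own currency", {
  m <- toy_macro()
  # identity year
  expect_equal(deflate(usd(100), 2019, m)$amount, 100)
  # 100 * 112.2 / 110.0 = 102.0, oracle: hand arithmetic
  expect_equal(deflate(usd(100, 2018), 2019, m)$amount, 102.0)
  # unit deflator ratio leaves the amount unchanged (XOF is flat)
  xof <- data.frame(amount = 5000, currency = "XOF", year = 2018L)
  expect_equal(deflate(xof, 2019, m)$amount, 5000)
  expect_error(deflate(usd(1, 1990), 2019, m), "USD.*1990")
})

test_that("to_usd divides by the exchange rate of the item's own year", {
  m <- toy_macro()
  vnd <- data.frame(amount = 23e6, currency = "VND", year = 2019L)
  expect_equal(to_usd(vnd, m)$amount, 1000)
  expect_equal(to_usd(usd(50), m)$amount, 50) # USD is a no-op
  zero <- data.frame(amount = 0, currency = "XOF", year = 2019L)
  expect_equal(to_usd(zero, m)$amount, 0)
})

test_that("normalize_money deflates locally first, then converts at the base-year rate", {
  m <- macro_table(tibble::tribble(
    ~currency, ~year, ~deflator, ~fx_per_usd,
    "USD", 2018L, 110.0, 1,
    "USD", 2019L, 112.2, 1,
    "XOF", 2018L, 100.0, 520,
    "XOF", 2019L, 102.0, 500
  ))
  # local 2018 item, deflator ratio 1.02, base-year fx 500:
  # 51 000 -> 52 020 local -> $104.04 (two-step hand arithmetic)
  x <- data.frame(amount = 51000, currency = "XOF", year = 2018L)
  out <- normalize_money(x, 2019, m)
  expect_equal(out$amount, 104.04)
  expect_equal(out$currency, "USD")
  # USD items are deflated only, never converted
  expect_equal(normalize_money(usd(100, 2018), 2019, m)$amount, 102.0)
  # local base-year item is converted only
  y <- data.frame(amount = 1000, currency = "XOF", year = 2019L)
  expect_equal(normalize_money(y, 2019, m)$amount, 2)
  # idempotent on already-normalized money
  expect_equal(normalize_money(out, 2019, m), out)
})

test_that("annualize_capital implements the equivalent annual cost", {
  expect_equal(annualize_capital(100, 1, valuation_params(discount_rate = 0)),
               100)
  # A = (1 - 1.03^-3) / 0.03 = 2.828611; 300 / A = 106.06
  expect_equal(annualize_capital(300, 3), 106.059109, tolerance = 1e-6)
  half <- valuation_params(survey_duration_months = 6)
  expect_equal(annualize_capital(300, 3, half),
               annualize_capital(300, 3) / 2)
  expect_error(annualize_capital(100, 0), "useful life")
})

test_that("annuity factor inverts: E * A recovers K over random (K, n, r)", {
  set.seed(42)
  for (i in 1:1000) {
    k <- stats::runif(1, 1, 1e5)
    n <- sample(1:15, 1)
    r <- stats::runif(1, 0, 0.2)
    p <- valuation_params(discount_rate = r)
    e <- annualize_capital(k, n, p)
    a <- if (r == 0) n else (1 - (1 + r)^(-n)) / r
    expect_equal(e * a, k, tolerance = 1e-9)
  }
})

test_that("equivalent annual cost is monotone in rate and life, with r->0 limit K/n", {
  lives <- c(1, 2, 3, 4, 10)
  rates <- c(0, 0.01, 0.03, 0.1)
  e <- outer(rates, lives, function(r, n) {
    purrr::map2_dbl(r, n, ~annualize_capital(1000, .y,
                                             valuation_params(discount_rate = .x)))
  })
  expect_true(all(diff(e) > 0)) # increasing in the discount rate
  expect_true(all(apply(e, 1, diff) < 0)) # decreasing in useful life
  tiny <- annualize_capital(1000, 4, valuation_params(discount_rate = 1e-9))
  expect_equal(tiny, 250, tolerance = 1e-6)
  # spreading over 2+ years at moderate rates never exceeds the purchase
  # price (at n = 1 with r > 0 the financing cost pushes E above K)
  expect_true(all(e[, lives >= 2] <= 1000 + 1e-9))
})

test_that("value_personnel prices minutes through the wage table", {
  m <- toy_macro()
  w <- toy_wages()
  item <- function(minutes, role, location) {
    tibble::tibble(role = role, location = location,
                   person_minutes = minutes)
  }
  expect_equal(value_personnel(item(480, "enumerator", "in_country"), w, m),
               80)
  expect_equal(value_personnel(item(240, "enumerator", "in_country"), w, m),
               40)
  # 46 000 XOF/day at 575 XOF/USD = $80/day
  expect_equal(value_personnel(item(480, "data_entry_clerk", "in_country"),
                               w, m), 80)
  expect_error(value_personnel(item(60, "chef", "in_country"), w, m),
               "no wage.*chef")
})

test_that("respondent participation cost follows the working-month convention", {
  expect_equal(respondent_cost(39, 151), 0.81)
  expect_equal(respondent_cost(47, 59), 0.36)
  expect_equal(respondent_cost(0, 100, consent_minutes = 0), 0)
  # brute-force oracle for the convention: minutes * wage / working minutes
  oracle <- (39 + 15) * 151 / (168 * 60)
  expect_equal(respondent_cost(39, 151), round(oracle + 1e-12, 2))
})

test_that("valued totals are invariant to item order and to item splitting", {
  fx <- study_fixture("vietnam")
  valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
  set.seed(1)
  shuf <- valued[sample(nrow(valued)), ]
  expect_equal(sum(shuf$cost_usd), sum(valued$cost_usd))
  # split one plain item in two equal halves and revalue
  led <- fx$ledger
  i <- which(led$cost_centre == "supplies")[1]
  half <- led[i, ]
  half$amount <- half$amount / 2
  half$id <- paste0(half$id, "_b")
  led$amount[i] <- led$amount[i] / 2
  led2 <- cost_ledger(dplyr::bind_rows(led, half))
  v2 <- value_ledger(led2, fx$wages, fx$macro)
  expect_equal(sum(v2$cost_usd), sum(valued$cost_usd), tolerance = 1e-12)
})

test_that("value_ledger refuses an invalid ledger and annualizes capital rows", {
  led <- toy_ledger()
  v <- value_ledger(led, toy_wages(), toy_macro())
  expect_equal(v$cost_usd[v$id == "p1"], 80) # 480 min at $80/day
  expect_equal(v$cost_usd[v$id == "k1"], 1000 / 2.828611, tolerance = 1e-6)
  expect_equal(v$cost_usd[v$id == "s1"], 100)
  bad <- led
  bad$role[1] <- NA
  expect_error(value_ledger(bad, toy_wages(), toy_macro()), "validation")
})
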