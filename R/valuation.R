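# Valuation: every cost item -> base-year USD ------------------------------

#' Valuation parameters
#'
#' The knobs of the valuation engine, with the study's conventions as
#' defaults: costs expressed in 2019 US dollars, capital equipment annualized
#' at a 3 % discount rate over its useful life, one person-day = 480 minutes
#' (8 h), respondent time priced against a 168 h working month (21 days of
#' 8 h), and the full annualized year attributed to the survey
#' (`survey_duration_months = 12`).
#'
#' @param base_year Calendar year all costs are expressed in.
#' @param discount_rate Annual discount rate used in the annuity factor.
#' @param day_minutes Minutes in one person-day.
#' @param hours_per_month Working hours per month used to convert a monthly
#'   minimum wage into a per-minute rate.
#' @param survey_duration_months Months of the annualized equipment year
#'   charged to the survey (12 = one full equivalent annual cost).
#' @param consent_minutes Minutes of respondent time for recruitment and
#'   consent added to the interview time.
#' @param shared_allocation How items used by both modalities enter each
#'   arm's total: `"duplicate"` charges the full cost to both arms (the
#'   study's convention), `"split"` charges half to each.
#' @return A list of class `valuation_params`.
#' @export
valuation_params <- function(base_year = 2019L,
                             discount_rate = 0.03,
                             day_minutes = 480,
                             hours_per_month = 168,
                             survey_duration_months = 12,
                             consent_minutes = 15,
                             shared_allocation = c("duplicate", "split")) {
  stopifnot(discount_rate >= 0, discount_rate < 1,
            day_minutes > 0, hours_per_month > 0,
            survey_duration_months > 0, survey_duration_months <= 12)
  structure(
    list(base_year = as.integer(base_year), discount_rate = discount_rate,
         day_minutes = day_minutes, hours_per_month = hours_per_month,
         survey_duration_months = survey_duration_months,
         consent_minutes = consent_minutes,
         shared_allocation = match.arg(shared_allocation)),
    class = "valuation_params"
  )
}

macro_lookup <- function(macro, what, currency, year) {
  i <- match(paste(currency, year), paste(macro$currency, macro$year))
  if (anyNA(i)) {
    miss <- which(is.na(i))[1]
    stop(sprintf("no macro %s entry for currency '%s', year %d",
                 what, currency[miss], year[miss]), call. = FALSE)
  }
  macro[[what]][i]
}

#' Deflate, convert and normalize money
#'
#' `deflate()` re-expresses an amount in the prices of `base_year` using the
#' GDP implicit price deflator of its own currency (amount ×
#' deflator(base)/deflator(year); currency unchanged). `to_usd()` converts an
#' amount to US dollars at the average exchange rate of its own year (amount
#' / fx_per_usd). `normalize_money()` composes them in the contractual order:
#' local-currency amounts are first deflated to the base year in local
#' currency, then converted at the base-year exchange rate; USD amounts are
#' deflated only and never touched by fx. All three are vectorised over data
#' frames carrying `amount`, `currency`, `year` columns.
#'
#' @param money Data frame with columns `amount`, `currency`, `year` (extra
#'   columns pass through untouched).
#' @param base_year Target year.
#' @param macro A [macro_table()].
#' @return The data frame with `amount`/`year` (and for conversion,
#'   `currency`) updated.
#' @export
#' @examples
#' macro <- macro_table(data.frame(
#'   currency = c("USD", "USD"), year = c(2018, 2019),
#'   deflator = c(110.0, 112.2), fx_per_usd = c(1, 1)
#' ))
#' deflate(data.frame(amount = 100, currency = "USD", year = 2018),
#'         2019, macro)$amount # 102.0
deflate <- function(money, base_year, macro) {
  d_from <- macro_lookup(macro, "deflator", money$currency, money$year)
  d_to <- macro_lookup(macro, "deflator", money$currency,
                       rep(as.integer(base_year), nrow(money)))
  money$amount <- money$amount * d_to / d_from
  money$year <- as.integer(base_year)
  money
}

#' @rdname deflate
#' @export
to_usd <- function(money, macro) {
  is_local <- money$currency != "USD"
  if (any(is_local)) {
    fx <- macro_lookup(macro, "fx_per_usd", money$currency[is_local],
                       money$year[is_local])
    money$amount[is_local] <- money$amount[is_local] / fx
    money$currency[is_local] <- "USD"
  }
  money
}

#' @rdname deflate
#' @export
normalize_money <- function(money, base_year, macro) {
  to_usd(deflate(money, base_year, macro), macro)
}

#' Equivalent annual cost of a capital purchase
#'
#' Spreads a capital purchase over its useful life with the annuity method:
#' the equivalent annual cost is `E = K / A` with annuity factor
#' `A = (1 - (1 + r)^-n) / r` (and `A = n` when `r = 0`). The cost charged to
#' the survey is `E * survey_duration_months / 12`.
#'
#' @param purchase Purchase price, already normalized to base-year USD
#'   (vectorised).
#' @param useful_life Useful life in whole years (vectorised).
#' @param params A [valuation_params()].
#' @return Survey-attributed annualized cost, same length as `purchase`.
#' @export
#' @examples
#' annualize_capital(300, 3) # 106.06 at the default 3 % rate
annualize_capital <- function(purchase, useful_life,
                              params = valuation_params()) {
  if (any(useful_life < 1)) stop("useful life must be at least one year")
  r <- params$discount_rate
  a <- if (r == 0) useful_life else (1 - (1 + r)^(-useful_life)) / r
  purchase / a * params$survey_duration_months / 12
}

#' Value personnel time from a wage table
#'
#' Personnel cost items are priced as `person_minutes / day_minutes *
#' wage_per_day`, with the wage looked up by (role, location) and normalized
#' to base-year USD through the macro table.
#'
#' @param items Personnel rows of a [cost_ledger()] (columns `role`,
#'   `location`, `person_minutes`).
#' @param wages A [wage_table()].
#' @param macro A [macro_table()].
#' @param params A [valuation_params()].
#' @return Numeric vector of base-year USD costs, one per row.
#' @export
value_personnel <- function(items, wages, macro, params = valuation_params()) {
  key <- paste(items$role, items$location)
  i <- match(key, paste(wages$role, wages$location))
  if (anyNA(i)) {
    miss <- which(is.na(i))[1]
    stop(sprintf("no wage for role '%s' at location '%s'",
                 items$role[miss], items$location[miss]), call. = FALSE)
  }
  wage_usd <- normalize_money(
    data.frame(amount = wages$wage_per_day[i],
               currency = wages$currency[i], year = wages$year[i]),
    params$base_year, macro
  )$amount
  items$person_minutes / params$day_minutes * wage_usd
}

#' Respondent participation cost
#'
#' Respondent time (interview plus recruitment/consent) valued at a minimum
#' monthly wage spread over a working month:
#' `(interview + consent) * monthly_wage / (hours_per_month * 60)`, rounded
#' to the cent for reporting.
#'
#' @param interview_minutes Average interview minutes per respondent.
#' @param consent_minutes Recruitment/consent minutes (default from
#'   `params`).
#' @param monthly_wage Minimum monthly wage in base-year USD.
#' @param params A [valuation_params()].
#' @return Cost per respondent in USD, rounded to cents.
#' @export
#' @examples
#' respondent_cost(39, monthly_wage = 151) # $0.81
respondent_cost <- function(interview_minutes,
                            monthly_wage,
                            consent_minutes = params$consent_minutes,
                            params = valuation_params()) {
  stopifnot(interview_minutes >= 0, consent_minutes >= 0, monthly_wage >= 0)
  per_min <- monthly_wage / (params$hours_per_month * 60)
  round_half_up((interview_minutes + consent_minutes) * per_min, 2)
}

# round half away from zero (the paper's presentation convention), unlike
# base round()'s round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Value every item of a cost ledger
#'
#' Runs the full valuation pipeline over a ledger: amounts are normalized to
#' base-year USD (deflate in own currency, then convert at the base-year
#' rate), capital items are annualized over their useful life, and personnel
#' items are priced from the wage table via their person-minutes. Quantities
#' multiply unit amounts for non-personnel items.
#'
#' @param ledger A validated [cost_ledger()].
#' @param wages A [wage_table()].
#' @param macro A [macro_table()].
#' @param params A [valuation_params()].
#' @return The ledger with a `cost_usd` column (base-year USD per row).
#' @export
value_ledger <- function(ledger, wages, macro, params = valuation_params()) {
  problems <- validate_ledger(ledger, macro = macro)
  if (nrow(problems) > 0) {
    stop("ledger fails validation (", nrow(problems), " problem(s)); first: ",
         problems$id[1], ": ", problems$problem[1], call. = FALSE)
  }
  pers <- ledger$cost_centre == "personnel"
  cost <- numeric(nrow(ledger))

  if (any(!pers)) {
    base <- normalize_money(
      data.frame(amount = ledger$amount[!pers] * ledger$quantity[!pers],
                 currency = ledger$currency[!pers],
                 year = ledger$year[!pers]),
      params$base_year, macro
    )$amount
    cap <- ledger$is_capital[!pers]
    base[cap] <- annualize_capital(base[cap],
                                   ledger$useful_life_years[!pers][cap],
                                   params)
    cost[!pers] <- base
  }
  if (any(pers)) {
    cost[pers] <- value_personnel(ledger[pers, ], wages, macro, params)
  }
  ledger$cost_usd <- cost
  ledger
}
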