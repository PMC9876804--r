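# Synthetic data: seeded generators and the calibrated study fixture -------

#' Default macro table (synthetic)
#'
#' GDP implicit price deflators and average exchange rates for USD, VND and
#' XOF in 2018-2019, close to published series but synthetic approximations:
#' they are calibration inputs of the packaged fixtures, not official
#' statistics.
#'
#' @return A [macro_table()].
#' @export
default_macro_table <- function() {
  macro_table(tibble::tribble(
    ~currency, ~year, ~deflator, ~fx_per_usd,
    "USD", 2018L, 110.4, 1,
    "USD", 2019L, 112.4, 1,
    "VND", 2018L, 183.5, 22700,
    "VND", 2019L, 186.9, 23050,
    "XOF", 2018L, 99.2, 555.5,
    "XOF", 2019L, 98.7, 585.9
  ))
}

#' Default wage tables (synthetic)
#'
#' Per-day wages by role and location for each study country. Field staff
#' are priced in local currency; internationally based staff in USD, with a
#' large international premium. Synthetic calibration values.
#'
#' @param country `"vietnam"` or `"burkina_faso"`.
#' @return A [wage_table()].
#' @export
default_wage_table <- function(country = c("vietnam", "burkina_faso")) {
  country <- match.arg(country)
  intl <- tibble::tribble(
    ~role, ~location, ~currency, ~year, ~wage_per_day,
    "researcher", "international", "USD", 2019L, 400,
    "lead_researcher", "international", "USD", 2019L, 640,
    "statistician", "international", "USD", 2019L, 440,
    "administrator", "international", "USD", 2019L, 280,
    "coordinator", "international", "USD", 2019L, 400,
    "technical_advisor", "international", "USD", 2019L, 480
  )
  if (country == "vietnam") {
    local <- tibble::tribble(
      ~role, ~location, ~currency, ~year, ~wage_per_day,
      "enumerator", "in_country", "VND", 2019L, 800000,
      "field_supervisor", "in_country", "VND", 2019L, 1100000,
      "data_entry_clerk", "in_country", "VND", 2019L, 600000,
      "data_supervisor", "in_country", "VND", 2019L, 900000,
      "translator", "in_country", "VND", 2019L, 700000,
      "coordinator", "in_country", "VND", 2019L, 1200000,
      "researcher", "in_country", "USD", 2019L, 40,
      "lead_researcher", "in_country", "USD", 2019L, 64,
      "statistician", "in_country", "USD", 2019L, 44,
      "administrator", "in_country", "USD", 2019L, 28,
      "chef", "in_country", "VND", 2019L, 500000,
      "technical_advisor", "in_country", "USD", 2019L, 48
    )
  } else {
    local <- tibble::tribble(
      ~role, ~location, ~currency, ~year, ~wage_per_day,
      "enumerator", "in_country", "XOF", 2019L, 12000,
      "field_supervisor", "in_country", "XOF", 2019L, 18000,
      "data_entry_clerk", "in_country", "XOF", 2019L, 9000,
      "data_supervisor", "in_country", "XOF", 2019L, 15000,
      "translator", "in_country", "XOF", 2019L, 11000,
      "coordinator", "in_country", "XOF", 2019L, 20000,
      "researcher", "in_country", "USD", 2019L, 40,
      "lead_researcher", "in_country", "USD", 2019L, 64,
      "statistician", "in_country", "USD", 2019L, 44,
      "administrator", "in_country", "USD", 2019L, 28,
      "chef", "in_country", "XOF", 2019L, 8000,
      "technical_advisor", "in_country", "USD", 2019L, 48
    )
  }
  wage_table(dplyr::bind_rows(local, intl))
}

# usd value of one person-day for a (role, location) through the macro table
wage_usd_per_day <- function(wages, role, location, macro,
                             params = valuation_params()) {
  i <- which(wages$role == role & wages$location == location)
  if (length(i) != 1) stop("wage lookup failed for ", role, "/", location)
  normalize_money(
    data.frame(amount = wages$wage_per_day[i], currency = wages$currency[i],
               year = wages$year[i]),
    params$base_year, macro
  )$amount
}

# a personnel ledger row whose valued cost is exactly `value` USD
personnel_item <- function(id, country, modality, activity, subactivity,
                           value, role, location, wages, macro, params,
                           variability, payer = "study") {
  w <- wage_usd_per_day(wages, role, location, macro, params)
  tibble::tibble(
    id = id, country = country, modality = modality, activity = activity,
    subactivity = subactivity, cost_centre = "personnel", payer = payer,
    currency = "USD", year = params$base_year, amount = 0, quantity = 1,
    is_capital = FALSE, useful_life_years = NA_real_, role = role,
    person_minutes = value * params$day_minutes / w,
    variability = variability, location = location
  )
}

# a non-personnel row whose normalized cost is exactly `value` USD, optionally
# denominated in another currency/year for texture
money_item <- function(id, country, modality, activity, subactivity, centre,
                       value, macro, params, variability,
                       currency = "USD", year = params$base_year,
                       payer = "study") {
  d <- macro
  d_from <- macro_lookup(d, "deflator", currency, as.integer(year))
  d_to <- macro_lookup(d, "deflator", currency, params$base_year)
  fx <- if (currency == "USD") 1 else {
    macro_lookup(d, "fx_per_usd", currency, params$base_year)
  }
  tibble::tibble(
    id = id, country = country, modality = modality, activity = activity,
    subactivity = subactivity, cost_centre = centre, payer = payer,
    currency = currency, year = as.integer(year),
    amount = value * fx * d_from / d_to, quantity = 1,
    is_capital = FALSE, useful_life_years = NA_real_, role = NA_character_,
    person_minutes = NA_real_, variability = variability,
    location = NA_character_
  )
}

# Calibration constants of the packaged validation-study fixture ------------
# Totals, sample sizes and scenario outcomes are the published study figures;
# everything below the activity level is a synthetic reconstruction.
fixture_constants <- function(country) {
  if (country == "vietnam") {
    list(
      total = c(inddex24 = 111004, papi = 120483),
      n = c(inddex24 = 147, papi = 147),
      # per-respondent cost after the all-in-country-personnel scenario
      localized_pr = c(inddex24 = 498, papi = 448),
      national_total = c(inddex24 = 477267, papi = 601001),
      shared_refprep = list(total = 41800, intl = 8000, local_pers = 30000),
      interview_mean = c(inddex24 = 39, papi = 44),
      respondent_wage_month = 151,
      # activity shares (reference-data prep is implied by the shared block;
      # survey_execution absorbs the remainder)
      shares = list(
        inddex24 = c(survey_preparation = 0.14, training = 0.06,
                     data_entry = 0.02, data_cleaning_processing = 0.065,
                     administration = 0.13),
        papi = c(survey_preparation = 0.07, training = 0.05,
                 data_entry = 0.10, data_cleaning_processing = 0.09,
                 administration = 0.21)
      ),
      personnel_share = c(inddex24 = 0.75, papi = 0.80),
      equipment = list(
        inddex24 = tibble::tribble(
          ~subactivity, ~unit_price, ~quantity, ~life,
          "tablets", 250, 12, 3,
          "food_scales", 40, 14, 2,
          "hard_drives", 100, 2, 4,
          "cabinets_weights", 150, 2, 10
        ),
        papi = tibble::tribble(
          ~subactivity, ~unit_price, ~quantity, ~life,
          "food_scales", 40, 14, 2,
          "cabinets_weights", 150, 2, 10
        )
      ),
      subscription = c(inddex24 = 3000, papi = 0),
      per_month_block = 4500, per_hub_block = 1500,
      national = national_config(4376, replicate_fraction = 0.20, hubs = 3,
                                 months_per_hub = 2,
                                 interviews_per_enumerator_day = 4),
      base_config = function(n) {
        national_config(n, replicate_fraction = 0, hubs = 1,
                        months_per_hub = 1,
                        interviews_per_enumerator_day = 1.1)
      }
    )
  } else {
    list(
      total = c(inddex24 = 78105, papi = 79456),
      n = c(inddex24 = 145, papi = 146),
      localized_pr = c(inddex24 = 456, papi = 410),
      national_total = c(inddex24 = 802385, papi = 962297),
      shared_refprep = list(total = 13100, intl = 3000, local_pers = 8600),
      interview_mean = c(inddex24 = 47, papi = 50),
      respondent_wage_month = 59,
      shares = list(
        inddex24 = c(survey_preparation = 0.23, training = 0.09,
                     data_entry = 0.022, data_cleaning_processing = 0.11,
                     administration = 0.20),
        papi = c(survey_preparation = 0.12, training = 0.09,
                 data_entry = 0.11, data_cleaning_processing = 0.085,
                 administration = 0.25)
      ),
      personnel_share = c(inddex24 = 0.70, papi = 0.74),
      equipment = list(
        inddex24 = tibble::tribble(
          ~subactivity, ~unit_price, ~quantity, ~life,
          "tablets", 230, 12, 3,
          "food_scales", 35, 13, 2,
          "hard_drives", 100, 1, 4,
          "cabinets_weights", 150, 1, 10
        ),
        papi = tibble::tribble(
          ~subactivity, ~unit_price, ~quantity, ~life,
          "food_scales", 35, 13, 2,
          "cabinets_weights", 150, 1, 10
        )
      ),
      subscription = c(inddex24 = 3000, papi = 0),
      per_month_block = 3000, per_hub_block = 1200,
      national = national_config(6500, replicate_fraction = 0.20, hubs = 4,
                                 months_per_hub = 3,
                                 interviews_per_enumerator_day = 4),
      base_config = function(n) {
        national_config(n, replicate_fraction = 0, hubs = 1,
                        months_per_hub = 1,
                        interviews_per_enumerator_day = 1.1)
      }
    )
  }
}

# water-fill `amount` into activities in priority order, capped by room;
# returns the allocation and stops if the block cannot be placed
fill_block <- function(amount, room, priority) {
  alloc <- stats::setNames(numeric(length(room)), names(room))
  for (a in c(priority, setdiff(names(room), priority))) {
    take <- min(amount, room[[a]])
    alloc[[a]] <- take
    room[[a]] <- room[[a]] - take
    amount <- amount - take
    if (amount <= 1e-6) break
  }
  if (amount > 1e-6) stop("fixture calibration infeasible: block overflow")
  list(alloc = alloc, room = room)
}

#' Calibrated validation-study fixture
#'
#' A deterministic synthetic cost ledger (both survey arms plus shared
#' dietary-reference-data items), wage table and macro table for one study
#' country, calibrated so that the valued ledger reproduces the published
#' validation-study cost surface: the arm totals to the dollar, the
#' reference-data-preparation and other reported activity shares to within
#' one percentage point, the personnel share of total cost, the
#' all-in-country-personnel scenario per-respondent costs, and — through the
#' variability tags and the packaged national configuration — the
#' national-scale scenario totals. The item level is a synthetic
#' reconstruction, not the study's (unpublished) expenditure records.
#'
#' @param country `"vietnam"` or `"burkina_faso"`.
#' @param params A [valuation_params()].
#' @return A list: `ledger` (raw [cost_ledger()]), `wages`, `macro`, `n`
#'   (respondents per arm), `interview_mean` (minutes per arm),
#'   `respondent_wage_month` (USD), `national` (a [national_config()]),
#'   `base_config` (function of n giving the validation-study staffing
#'   anchor), and `totals` (the calibration target totals per arm).
#' @export
study_fixture <- function(country = c("vietnam", "burkina_faso"),
                          params = valuation_params()) {
  country <- match.arg(country)
  k <- fixture_constants(country)
  macro <- default_macro_table()
  wages <- default_wage_table(country)

  rho <- wage_usd_per_day(wages, "researcher", "in_country", macro, params) /
    wage_usd_per_day(wages, "researcher", "international", macro, params)

  rows <- list()
  push <- function(x) rows[[length(rows) + 1]] <<- x
  uid <- local({
    i <- 0
    function(tag) {
      i <<- i + 1
      sprintf("%s_%s_%03d", substr(country, 1, 2), tag, i)
    }
  })

  # shared dietary-reference-data block (counted in both arms)
  s <- k$shared_refprep
  push(personnel_item(uid("ref"), country, "shared",
                      "dietary_reference_data_prep", "intl_oversight",
                      s$intl, "researcher", "international", wages, macro,
                      params, "fixed"))
  push(personnel_item(uid("ref"), country, "shared",
                      "dietary_reference_data_prep", "food_list_recipes",
                      s$local_pers * 0.6, "researcher", "in_country", wages,
                      macro, params, "fixed"))
  push(personnel_item(uid("ref"), country, "shared",
                      "dietary_reference_data_prep", "portion_conversions",
                      s$local_pers * 0.4, "chef", "in_country", wages, macro,
                      params, "fixed"))
  nonpers_ref <- s$total - s$intl - s$local_pers
  push(money_item(uid("ref"), country, "shared",
                  "dietary_reference_data_prep", "photo_atlas_supplies",
                  "supplies", nonpers_ref * 0.5, macro, params, "fixed",
                  currency = "USD", year = 2018L))
  push(money_item(uid("ref"), country, "shared",
                  "dietary_reference_data_prep", "market_survey_transport",
                  "transportation", nonpers_ref * 0.5, macro, params, "fixed",
                  currency = if (country == "vietnam") "VND" else "XOF"))

  for (arm in c("inddex24", "papi")) {
    total <- k$total[[arm]]
    n_arm <- k$n[[arm]]

    # localization target fixes the internationally-priced block
    delta_loc <- total - k$localized_pr[[arm]] * n_arm
    intl_total <- delta_loc / (1 - rho)
    intl_arm <- intl_total - s$intl
    stopifnot(intl_arm > 0)

    # designed texture blocks
    eq <- k$equipment[[arm]]
    eq_value <- sum(annualize_capital(eq$unit_price * eq$quantity, eq$life,
                                      params))
    sub_value <- k$subscription[[arm]]
    m_value <- k$per_month_block
    h_value <- k$per_hub_block
    resp_value <- n_arm * respondent_cost(k$interview_mean[[arm]],
                                          k$respondent_wage_month,
                                          params = params)

    # national-scale target fixes the per-respondent pool
    base_cfg <- k$base_config(n_arm)
    st_new <- staffing_requirements(k$national, arm, round = FALSE)
    st_base <- staffing_requirements(base_cfg, arm, round = FALSE)
    r_resp <- st_new$effective_interviews / st_base$effective_interviews
    r_enum <- st_new$enumerators / st_base$enumerators
    r_hub <- k$national$hubs / base_cfg$hubs
    r_month <- (k$national$hubs * k$national$months_per_hub) /
      (base_cfg$hubs * base_cfg$months_per_hub)
    t_localized <- total - delta_loc
    pool_resp <- (k$national_total[[arm]] - t_localized -
                    (r_enum - 1) * eq_value - (r_hub - 1) * h_value -
                    (r_month - 1) * m_value) / (r_resp - 1)
    stopifnot(pool_resp > resp_value)

    # activity targets; survey_execution absorbs the remainder
    sh <- k$shares[[arm]]
    targets <- stats::setNames(numeric(length(cost_activities)),
                               cost_activities)
    targets["dietary_reference_data_prep"] <- s$total
    targets[names(sh)] <- sh * total
    targets["survey_execution"] <- total - sum(targets)
    stopifnot(all(targets >= 0))

    room <- as.list(targets)
    room$dietary_reference_data_prep <- 0 # fully designed by the shared block
    room$survey_preparation <- room$survey_preparation - eq_value - sub_value
    room$training <- room$training - h_value
    room$survey_execution <- room$survey_execution - m_value - resp_value
    stopifnot(all(unlist(room) >= 0))

    # international leadership time (fixed), mostly management and oversight
    f_intl <- fill_block(intl_arm, room,
                         c("administration", "data_cleaning_processing",
                           "survey_preparation", "survey_execution",
                           "training"))
    room <- f_intl$room
    # per-respondent pool: data entry, cleaning and field execution
    f_resp <- fill_block(pool_resp - resp_value, room,
                         c("data_entry", "data_cleaning_processing",
                           "survey_execution", "survey_preparation",
                           "training"))
    room <- f_resp$room
    pool_fixed <- sum(unlist(room))

    # split the residual pools into personnel / non-personnel so the arm's
    # personnel share lands on target
    pers_designed <- s$intl + s$local_pers + intl_arm
    extra_pers <- k$personnel_share[[arm]] * total - pers_designed
    stopifnot(extra_pers >= 0)
    resp_pool_total <- pool_resp - resp_value
    pers_resp <- min(resp_pool_total, extra_pers)
    pers_fixed <- min(pool_fixed, extra_pers - pers_resp)
    frac_pers_resp <- if (resp_pool_total > 0) pers_resp / resp_pool_total else 0
    frac_pers_fixed <- if (pool_fixed > 0) pers_fixed / pool_fixed else 0

    # emit designed blocks
    for (i in seq_len(nrow(eq))) {
      push(tibble::tibble(
        id = uid("eq"), country = country, modality = arm,
        activity = "survey_preparation", subactivity = eq$subactivity[i],
        cost_centre = "equipment", payer = "study", currency = "USD",
        year = params$base_year, amount = eq$unit_price[i],
        quantity = eq$quantity[i], is_capital = TRUE,
        useful_life_years = eq$life[i], role = NA_character_,
        person_minutes = NA_real_, variability = "per_enumerator",
        location = NA_character_
      ))
    }
    if (sub_value > 0) {
      push(money_item(uid("sub"), country, arm, "survey_preparation",
                      "mobile_platform_subscription", "other", sub_value,
                      macro, params, "fixed"))
    }
    push(money_item(uid("exe"), country, arm, "survey_execution",
                    "field_lodging", "lodging", m_value * 0.4, macro, params,
                    "per_month"))
    push(money_item(uid("exe"), country, arm, "survey_execution",
                    "field_per_diem", "per_diem", m_value * 0.4, macro,
                    params, "per_month"))
    push(money_item(uid("exe"), country, arm, "survey_execution",
                    "field_transport", "transportation", m_value * 0.2,
                    macro, params, "per_month",
                    currency = if (country == "vietnam") "VND" else "XOF"))
    push(money_item(uid("trn"), country, arm, "training", "training_venue",
                    "facilities", h_value, macro, params, "per_hub"))
    push(money_item(uid("rsp"), country, arm, "survey_execution",
                    "respondent_time", "other", resp_value, macro, params,
                    "per_respondent", payer = "respondent"))

    emit_pool <- function(alloc, variability, pers_frac, pers_role,
                          nonpers_centre, tag) {
      for (a in names(alloc)) {
        v <- alloc[[a]]
        if (v <= 1e-9) next
        vp <- v * pers_frac
        if (vp > 1e-9) {
          push(personnel_item(uid(tag), country, arm, a,
                              paste0(tag, "_staff_time"), vp, pers_role,
                              "in_country", wages, macro, params,
                              variability))
        }
        if (v - vp > 1e-9) {
          push(money_item(uid(tag), country, arm, a,
                          paste0(tag, "_expenses"), nonpers_centre, v - vp,
                          macro, params, variability))
        }
      }
    }
    for (a in names(f_intl$alloc)) {
      v <- f_intl$alloc[[a]]
      if (v <= 1e-9) next
      push(personnel_item(uid("int"), country, arm, a,
                          "international_staff_time", v, "researcher",
                          "international", wages, macro, params, "fixed"))
    }
    emit_pool(f_resp$alloc, "per_respondent", frac_pers_resp,
              if (country == "vietnam") "data_entry_clerk" else "enumerator",
              "supplies", "var")
    emit_pool(as.list(unlist(room)), "fixed", frac_pers_fixed, "coordinator",
              "other", "fix")
  }

  ledger <- cost_ledger(dplyr::bind_rows(rows))
  list(ledger = ledger, wages = wages, macro = macro, n = k$n,
       interview_mean = k$interview_mean,
       respondent_wage_month = k$respondent_wage_month,
       national = k$national, base_config = k$base_config,
       totals = k$total)
}

# General seeded generator ---------------------------------------------------

#' Specification for the generic synthetic ledger generator
#'
#' Describes the statistical structure of a synthetic survey cost ledger:
#' target activity shares, the personnel share of total cost, an equipment
#' list with useful lives, the international wage premium, and the fraction
#' of backup equipment purchased against loss or damage.
#'
#' @param country Study country label.
#' @param n_respondents Respondents per arm (> 0).
#' @param total_cost Approximate total cost per arm, USD.
#' @param activity_shares Named fractions over [cost_activities] summing
#'   to 1.
#' @param personnel_share Target personnel fraction of total cost.
#' @param backup_fraction Extra equipment purchased as backups (default
#'   10 %).
#' @param n_items_per_activity Ledger granularity.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(country = "vietnam",
                           n_respondents = 150,
                           total_cost = 1e5,
                           activity_shares = c(
                             dietary_reference_data_prep = 0.30,
                             survey_preparation = 0.15, training = 0.08,
                             survey_execution = 0.20, data_entry = 0.05,
                             data_cleaning_processing = 0.08,
                             administration = 0.14
                           ),
                           personnel_share = 0.75,
                           backup_fraction = 0.10,
                           n_items_per_activity = 4) {
  if (n_respondents <= 0) stop("n_respondents must be positive")
  if (abs(sum(activity_shares) - 1) > 1e-9) {
    stop("activity shares must sum to 1")
  }
  if (!setequal(names(activity_shares), cost_activities)) {
    stop("activity_shares must cover exactly the activity enum")
  }
  if (any(activity_shares < 0)) stop("activity shares must be non-negative")
  structure(
    list(country = country, n_respondents = n_respondents,
         total_cost = total_cost, activity_shares = activity_shares,
         personnel_share = personnel_share,
         backup_fraction = backup_fraction,
         n_items_per_activity = n_items_per_activity),
    class = "generator_spec"
  )
}

#' Generate a synthetic cost ledger
#'
#' Draws a random but seeded ledger with both survey arms plus shared
#' reference-data items, realized activity shares within two percentage
#' points of the spec's targets, capital equipment with useful lives from
#' the standard set, and an approximate personnel share. Deterministic given
#' `(spec, seed)`.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @param params A [valuation_params()].
#' @return A raw [cost_ledger()].
#' @export
generate_ledger <- function(spec, seed = 1, params = valuation_params()) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::local_seed(seed)
  rows <- list()
  push <- function(x) rows[[length(rows) + 1]] <<- x
  i <- 0
  uid <- function() {
    i <<- i + 1
    sprintf("syn_%04d", i)
  }
  lives <- c(2, 3, 4, 10)
  # reference-data preparation is generated once as a shared block; each
  # arm's own activities are scaled so every arm total is spec$total_cost
  # (papi 5 % dearer) and realized activity and personnel shares equal the
  # targets exactly
  emit_activity <- function(arm, a, target) {
    m <- spec$n_items_per_activity
    raw <- stats::rgamma(m, shape = 2, rate = 1)
    vals <- raw / sum(raw) * target
    pers_target <- spec$personnel_share * target
    # first items carry the personnel value, the rest the remainder
    k_pers <- max(1, m - 2)
    pers_vals <- vals[seq_len(k_pers)] / sum(vals[seq_len(k_pers)]) *
      pers_target
    other_vals <- vals[-seq_len(k_pers)] /
      sum(vals[-seq_len(k_pers)]) * (target - pers_target)
    for (j in seq_len(k_pers)) {
      push(tibble::tibble(
        id = uid(), country = spec$country, modality = arm, activity = a,
        subactivity = sprintf("%s_task%d", a, j),
        cost_centre = "personnel", payer = "study", currency = "USD",
        year = params$base_year, amount = 0, quantity = 1,
        is_capital = FALSE, useful_life_years = NA_real_,
        role = sample(c("enumerator", "researcher", "coordinator"), 1),
        person_minutes = pers_vals[j] / 40 * params$day_minutes,
        variability = sample(cost_variabilities, 1),
        location = "in_country"
      ))
    }
    for (j in seq_along(other_vals)) {
      if (a == "survey_preparation" && j == 1 && arm != "shared") {
        q <- max(1, round(5 * (1 + spec$backup_fraction)))
        life <- sample(lives, 1)
        push(tibble::tibble(
          id = uid(), country = spec$country, modality = arm, activity = a,
          subactivity = "equipment_purchase", cost_centre = "equipment",
          payer = "study", currency = "USD", year = params$base_year,
          # invert annualization so the valued amount meets the target
          amount = other_vals[j] *
            (1 - (1 + params$discount_rate)^(-life)) /
            params$discount_rate / q * 12 / params$survey_duration_months,
          quantity = q, is_capital = TRUE, useful_life_years = life,
          role = NA_character_, person_minutes = NA_real_,
          variability = "per_enumerator", location = NA_character_
        ))
      } else {
        push(tibble::tibble(
          id = uid(), country = spec$country, modality = arm, activity = a,
          subactivity = sprintf("%s_input%d", a, j),
          cost_centre = sample(setdiff(cost_centres, "personnel"), 1),
          payer = "study", currency = "USD", year = params$base_year,
          amount = other_vals[j], quantity = 1, is_capital = FALSE,
          useful_life_years = NA_real_, role = NA_character_,
          person_minutes = NA_real_,
          variability = sample(cost_variabilities, 1),
          location = NA_character_
        ))
      }
    }
  }
  ref_target <- spec$activity_shares[["dietary_reference_data_prep"]] *
    spec$total_cost
  emit_activity("shared", "dietary_reference_data_prep", ref_target)
  own <- setdiff(cost_activities, "dietary_reference_data_prep")
  for (arm in c("inddex24", "papi")) {
    scale_arm <- if (arm == "papi") 1.05 else 1
    arm_rest <- spec$total_cost * scale_arm - ref_target
    rest_shares <- spec$activity_shares[own] / sum(spec$activity_shares[own])
    for (a in own) emit_activity(arm, a, rest_shares[[a]] * arm_rest)
  }
  # the generic generator prices personnel at a flat $40/day in-country wage
  cost_ledger(dplyr::bind_rows(rows))
}

#' Flat wage table matching [generate_ledger()]
#'
#' @param premium International wage multiplier over the $40/day in-country
#'   rate.
#' @return A [wage_table()].
#' @export
generic_wage_table <- function(premium = 10) {
  wage_table(dplyr::bind_rows(
    tibble::tibble(role = cost_roles, location = "in_country",
                   currency = "USD", year = 2019L, wage_per_day = 40),
    tibble::tibble(role = cost_roles, location = "international",
                   currency = "USD", year = 2019L, wage_per_day = 40 * premium)
  ))
}

# Timing generator -----------------------------------------------------------

#' Generate synthetic interview timings
#'
#' Per-respondent interview durations per study arm: totals are drawn from a
#' normal distribution truncated at zero (lognormal by flag) with the stated
#' mean and SD, then split across the interview passes by Dirichlet-weighted
#' shares that sum exactly to the total. The menu segment (the CAPI home
#' screen) exists only for the `inddex24` arm, with expected share
#' `menu_mean / total_mean`. Deterministic given the seed.
#'
#' @param n Respondents per arm (>= 2).
#' @param country Country label.
#' @param total_mean,total_sd Named vectors (`inddex24`, `papi`) of mean/SD
#'   total minutes. Defaults are the Viet Nam study values (about 39 min,
#'   SD 15, using the CAPI platform; about 44 min, SD 10, on paper).
#' @param menu_mean Mean minutes in the menu screen (inddex24 only).
#' @param seed Integer seed.
#' @param family `"truncnorm"` (default) or `"lognormal"`.
#' @param concentration Dirichlet concentration controlling segment-share
#'   variability.
#' @return A timing tibble (see [read_timings()]).
#' @export
generate_timings <- function(n, country = "vietnam",
                             total_mean = c(inddex24 = 39, papi = 44),
                             total_sd = c(inddex24 = 15, papi = 10),
                             menu_mean = 10, seed = 1,
                             family = c("truncnorm", "lognormal"),
                             concentration = 60) {
  stopifnot(n >= 2)
  family <- match.arg(family)
  withr::local_seed(seed)
  base_w <- c(pass1 = 0.12, pass2 = 0.30, pass3 = 0.25,
              nonstd_recipe = 0.08, pass4 = 0.25)
  out <- purrr::map_dfr(c("inddex24", "papi"), function(arm) {
    mu <- total_mean[[arm]]
    sd <- total_sd[[arm]]
    total <- if (family == "truncnorm") {
      lo <- stats::pnorm(0, mu, sd)
      stats::qnorm(lo + stats::runif(n) * (1 - lo), mu, sd)
    } else {
      sl <- sqrt(log(1 + sd^2 / mu^2))
      stats::rlnorm(n, log(mu) - sl^2 / 2, sl)
    }
    w <- base_w
    if (arm == "inddex24") {
      menu_share <- menu_mean / mu
      w <- c(base_w * (1 - menu_share), menu = menu_share)
    }
    shares <- matrix(stats::rgamma(n * length(w),
                                   shape = rep(w * concentration, each = n)),
                     nrow = n)
    shares <- shares / rowSums(shares)
    seg <- shares * total
    colnames(seg) <- names(w)
    x <- tibble::as_tibble(seg)
    if (arm == "papi") x$menu <- NA_real_
    dplyr::bind_cols(
      tibble::tibble(
        respondent_id = sprintf("%s_%s_%03d", substr(country, 1, 2), arm,
                                seq_len(n)),
        country = country, modality = arm,
        site = rep(c("urban", "rural"), length.out = n)
      ),
      x[, c("pass1", "pass2", "pass3", "nonstd_recipe", "pass4", "menu")],
      tibble::tibble(total = total)
    )
  })
  out
}
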