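# Counterfactual scenarios --------------------------------------------------

#' Scale dietary-reference-data preparation by a borrowing fraction
#'
#' Counterfactual in which a fraction of the dietary reference data (food
#' lists, standard recipes, conversion factors, portion-size estimation
#' methods) is borrowed from a shared repository instead of being developed
#' from scratch, so the cost of the reference-data preparation activity in
#' the CAPI arm falls proportionally. Only items contributing to the
#' `inddex24` arm are scaled; the `papi` arm is left unchanged, so shared
#' reference-data items are first split into explicit per-arm copies (at full
#' cost each under the `"duplicate"` allocation rule, half each under
#' `"split"`).
#'
#' Both the monetary amount and the person-minutes of affected items are
#' scaled, so the rule holds whether items are priced directly or through
#' the wage table.
#'
#' @param ledger A [cost_ledger()] (raw, not yet valued).
#' @param borrow_fraction Fraction of reference-data preparation avoided, in
#'   \[0, 1\].
#' @param params A [valuation_params()] (shared-item allocation rule).
#' @return The transformed ledger.
#' @export
apply_fmdb_borrow <- function(ledger, borrow_fraction,
                              params = valuation_params()) {
  if (borrow_fraction < 0 || borrow_fraction > 1) {
    stop("borrow_fraction must be in [0, 1]")
  }
  refprep <- ledger$activity == "dietary_reference_data_prep"
  shared <- refprep & ledger$modality == "shared"
  if (any(shared)) {
    # materialise the shared reference-data items per arm so only the
    # inddex24 copy is scaled
    half <- if (params$shared_allocation == "split") 0.5 else 1
    copies <- purrr::map_dfr(c("inddex24", "papi"), function(m) {
      x <- ledger[shared, ]
      x$modality <- m
      x$id <- paste0(x$id, "_", m)
      x$amount <- x$amount * half
      x$person_minutes <- x$person_minutes * half
      x
    })
    ledger <- dplyr::bind_rows(ledger[!shared, ], copies)
    refprep <- ledger$activity == "dietary_reference_data_prep"
  }
  hit <- refprep & ledger$modality == "inddex24"
  ledger$amount[hit] <- ledger$amount[hit] * (1 - borrow_fraction)
  ledger$person_minutes[hit] <- ledger$person_minutes[hit] * (1 - borrow_fraction)
  ledger
}

#' Default substitution map for the localization scenario
#'
#' Maps each internationally based role to the in-country position used to
#' re-value its time. By default each role is mapped to the same role key at
#' the in-country wage.
#'
#' @param roles Character vector of international roles to map.
#' @return A named character vector (international role -> in-country role).
#' @export
default_role_substitutions <- function(roles = c("lead_researcher",
                                                 "researcher", "statistician",
                                                 "administrator",
                                                 "coordinator")) {
  stats::setNames(roles, roles)
}

#' Re-value international personnel at in-country wages
#'
#' Counterfactual in which every position filled by internationally based
#' personnel is instead filled by the equivalent in-country position: the
#' affected personnel items keep their person-minutes but are re-priced at
#' the substituted in-country wage at valuation time. Non-personnel items are
#' untouched.
#'
#' @param ledger A [cost_ledger()].
#' @param role_substitutions Named character vector mapping international
#'   roles to in-country roles (see [default_role_substitutions()]).
#' @return The transformed ledger (affected items have
#'   `location = "in_country"` and the substituted role).
#' @export
apply_localization <- function(ledger,
                               role_substitutions = default_role_substitutions()) {
  intl <- ledger$cost_centre == "personnel" &
    !is.na(ledger$location) & ledger$location == "international"
  roles <- unique(ledger$role[intl])
  missing_roles <- setdiff(roles, names(role_substitutions))
  if (length(missing_roles) > 0) {
    stop("no in-country substitution for international role(s): ",
         paste(missing_roles, collapse = ", "))
  }
  ledger$role[intl] <- unname(role_substitutions[ledger$role[intl]])
  ledger$location[intl] <- "in_country"
  ledger
}

#' National-scale scenario configuration
#'
#' Assumptions of the national-survey counterfactual: the national sample of
#' women of reproductive age, the fraction receiving a replicate recall on a
#' non-consecutive day, the number of subnational coordination hubs, the
#' months of simultaneous data collection per hub, interviewer productivity
#' and the supervision ratios.
#'
#' @param n_respondents National sample size.
#' @param replicate_fraction Fraction of respondents receiving a repeat
#'   recall (inflates the effective interview count).
#' @param hubs Number of subnational hubs.
#' @param months_per_hub Months of data collection per hub.
#' @param interviews_per_enumerator_day Completed recalls per enumerator-day.
#' @param working_days_per_month Working days per month for staffing.
#' @param supervisor_ratio Enumerators per field supervisor.
#' @param clerk_ratio Data-entry clerks per data supervisor.
#' @param entries_per_clerk_day Interviews a clerk keys (incl. double entry)
#'   per day; drives PAPI data-entry staffing.
#' @param capacity_building_included Whether capacity-building time/expenses
#'   are retained (default `FALSE`: the national team is assumed able to run
#'   the survey without external support).
#' @return A list of class `national_config`.
#' @export
national_config <- function(n_respondents,
                            replicate_fraction = 0.20,
                            hubs = 1,
                            months_per_hub = 1,
                            interviews_per_enumerator_day = 4,
                            working_days_per_month = 22,
                            supervisor_ratio = 6,
                            clerk_ratio = 10,
                            entries_per_clerk_day = 8,
                            capacity_building_included = FALSE) {
  stopifnot(n_respondents >= 1, replicate_fraction >= 0,
            replicate_fraction <= 1, hubs >= 1, months_per_hub > 0,
            interviews_per_enumerator_day > 0, supervisor_ratio >= 1,
            clerk_ratio >= 1, entries_per_clerk_day > 0)
  structure(
    list(n_respondents = n_respondents,
         replicate_fraction = replicate_fraction, hubs = hubs,
         months_per_hub = months_per_hub,
         interviews_per_enumerator_day = interviews_per_enumerator_day,
         working_days_per_month = working_days_per_month,
         supervisor_ratio = supervisor_ratio, clerk_ratio = clerk_ratio,
         entries_per_clerk_day = entries_per_clerk_day,
         capacity_building_included = capacity_building_included),
    class = "national_config"
  )
}

#' Staffing requirements of a survey configuration
#'
#' Full-time-equivalent staffing implied by a [national_config()]: effective
#' interviews are `n_respondents * (1 + replicate_fraction)`; enumerator FTEs
#' are effective interviews divided by interviewer throughput (interviews per
#' day x working days per month x months per hub); field supervisors follow
#' the 1:6 supervisor ratio. Data entry is modality-asymmetric: with
#' electronic capture (`inddex24`) no data-entry clerks are needed and one
#' data supervisor per hub performs ongoing electronic data monitoring; with
#' pen-and-paper (`papi`) clerks key the forms at `entries_per_clerk_day` and
#' data supervisors follow the 1:10 clerk ratio.
#'
#' @param config A [national_config()].
#' @param modality `"inddex24"` or `"papi"`.
#' @param round Round FTEs to the nearest whole number (reporting
#'   convention); internal scaling uses unrounded FTEs.
#' @return A list with `effective_interviews`, `enumerators`,
#'   `field_supervisors`, `data_entry_clerks`, `data_supervisors`.
#' @export
staffing_requirements <- function(config, modality = c("inddex24", "papi"),
                                  round = TRUE) {
  modality <- match.arg(modality)
  eff <- config$n_respondents * (1 + config$replicate_fraction)
  throughput <- config$interviews_per_enumerator_day *
    config$working_days_per_month * config$months_per_hub
  enum <- eff / throughput
  sup <- enum / config$supervisor_ratio
  if (modality == "papi") {
    clerks <- eff / (config$entries_per_clerk_day *
                       config$working_days_per_month * config$months_per_hub)
    dsup <- clerks / config$clerk_ratio
  } else {
    clerks <- 0
    dsup <- config$hubs # electronic data monitoring, one per hub
  }
  r <- if (round) function(x) round_half_up(x) else identity
  list(effective_interviews = eff,
       enumerators = r(enum), field_supervisors = r(sup),
       data_entry_clerks = r(clerks), data_supervisors = r(dsup))
}

#' Project a validation-scale ledger to national scale
#'
#' Scales a valued (and typically localized) ledger to the conditions of a
#' national survey using each item's cost-variability class: `fixed` items
#' are carried at base cost; `per_respondent` items scale with the effective
#' interview ratio; `per_enumerator` items (e.g. tablets and scales, one set
#' per interviewer plus backups) scale with the enumerator-FTE ratio so
#' equipment quantities are re-derived from the staffing model;
#' `per_hub` items scale with the hub count and `per_month` items with total
#' field months. Items flagged as capacity building (subactivity containing
#' `"capacity_building"`) are dropped unless the config retains them.
#'
#' @param valued A valued ledger (one country; both arms plus shared items).
#' @param config A [national_config()] describing the national survey.
#' @param base_config A [national_config()] describing the base study the
#'   ledger was costed under (its staffing model anchors the scaling
#'   ratios).
#' @param country Country to project.
#' @param modality Arm to project.
#' @param params A [valuation_params()].
#' @return A list with the projected arm ledger (`ledger`), its
#'   `ledger_summary` (`summary`), and the staffing block (`staffing`).
#' @export
project_national <- function(valued, config, base_config, country,
                             modality = c("inddex24", "papi"),
                             params = valuation_params()) {
  modality <- match.arg(modality)
  stopifnot(inherits(config, "national_config"),
            inherits(base_config, "national_config"))
  x <- arm_slice(valued, country, modality, params$shared_allocation)
  untagged <- which(is.na(x$variability))
  if (length(untagged) > 0) {
    stop("items without a variability tag: ",
         paste(utils::head(x$id[untagged], 5), collapse = ", "))
  }
  if (!config$capacity_building_included) {
    cb <- !is.na(x$subactivity) & grepl("capacity_building", x$subactivity)
    x <- x[!cb, ]
  }
  new_staff <- staffing_requirements(config, modality, round = FALSE)
  base_staff <- staffing_requirements(base_config, modality, round = FALSE)
  ratios <- c(
    fixed = 1,
    per_respondent = new_staff$effective_interviews /
      base_staff$effective_interviews,
    per_enumerator = new_staff$enumerators / base_staff$enumerators,
    per_hub = config$hubs / base_config$hubs,
    per_month = (config$hubs * config$months_per_hub) /
      (base_config$hubs * base_config$months_per_hub)
  )
  x$cost_usd <- x$cost_usd * unname(ratios[x$variability])
  # the projected slice is already arm-allocated; relabel shared rows so the
  # summary does not double-allocate them
  x$modality <- modality
  summary <- summarize_ledger(x, country, modality,
                              n_respondents = config$n_respondents,
                              params = params)
  list(ledger = x, summary = summary,
       staffing = staffing_requirements(config, modality, round = TRUE))
}

#' Percentage decrease between two per-respondent costs
#'
#' Convenience for scenario reporting: the percentage decrease from a
#' baseline per-respondent cost to a scenario per-respondent cost, rounded to
#' the nearest whole percent.
#'
#' @param from Baseline cost per respondent.
#' @param to Scenario cost per respondent.
#' @return Percentage decrease (positive when `to < from`).
#' @export
#' @examples
#' pct_decrease(755, 498) # 34
pct_decrease <- function(from, to) {
  round_half_up((from - to) / from * 100)
}
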