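# Analysis pipelines ---------------------------------------------------------

#' Run the primary cost analysis for one country
#'
#' Chains the full pipeline: validate, value, summarize both arms from the
#' societal perspective, compute the arm difference, the activity-layout cost
#' report, the tidy time/non-time data and the respondent participation
#' costs.
#'
#' @param ledger Raw [cost_ledger()] for one country (both arms + shared).
#' @param wages A [wage_table()].
#' @param macro A [macro_table()].
#' @param n Named vector of respondents per arm
#'   (`c(inddex24 = ..., papi = ...)`).
#' @param country Country analysed.
#' @param interview_mean Named vector of mean interview minutes per arm
#'   (used for respondent participation costs); optional.
#' @param respondent_wage_month Minimum monthly wage (base-year USD) for
#'   respondent time; optional.
#' @param params A [valuation_params()].
#' @return A list of class `primary_analysis`: `summaries` (per arm),
#'   `difference`, `report` (activity table), `time_nontime`,
#'   `respondent_costs`, `params_used`.
#' @export
run_primary_analysis <- function(ledger, wages, macro, n, country,
                                 interview_mean = NULL,
                                 respondent_wage_month = NULL,
                                 params = valuation_params()) {
  problems <- validate_ledger(ledger, macro = macro)
  if (nrow(problems) > 0) {
    stop("ledger validation failed: ",
         paste(utils::head(paste(problems$id, problems$problem), 3),
               collapse = "; "), call. = FALSE)
  }
  valued <- value_ledger(ledger, wages, macro, params)
  summaries <- purrr::map(
    stats::setNames(c("inddex24", "papi"), c("inddex24", "papi")),
    ~summarize_ledger(valued, country, .x, n[[.x]], params = params)
  )
  respondent_costs <- NULL
  if (!is.null(interview_mean) && !is.null(respondent_wage_month)) {
    respondent_costs <- tibble::tibble(
      modality = names(interview_mean),
      interview_minutes = unname(interview_mean),
      cost_per_respondent = respondent_cost(
        unname(interview_mean), respondent_wage_month, params = params
      )
    )
  }
  structure(
    list(
      country = country,
      summaries = summaries,
      difference = arm_difference(summaries$inddex24, summaries$papi),
      report = cost_report(summaries$inddex24, summaries$papi),
      time_nontime = time_nontime_report(valued, country, params),
      respondent_costs = respondent_costs,
      valued = valued,
      params_used = params
    ),
    class = "primary_analysis"
  )
}

#' @export
print.primary_analysis <- function(x, ...) {
  cat(sprintf("<primary_analysis> %s\n", x$country))
  for (m in names(x$summaries)) {
    s <- x$summaries[[m]]
    cat(sprintf("  per_respondent %s %d\n", m,
                round_half_up(s$per_respondent)))
  }
  cat(sprintf("  per-respondent difference (inddex24 - papi): %d\n",
              x$difference$per_respondent))
  invisible(x)
}

#' Run the three counterfactual scenarios
#'
#' Applies the scenario engine to a raw ledger: the reference-data borrowing
#' sweep (default fractions 25/50/75 %), the all-in-country-personnel
#' re-pricing, and (when configs are given) the national-scale projection.
#'
#' @inheritParams run_primary_analysis
#' @param borrow_fractions Borrowing fractions to sweep.
#' @param role_substitutions See [apply_localization()].
#' @param national A [national_config()], or `NULL` to skip the national
#'   scenario.
#' @param base_config Function of arm n returning the base-study
#'   [national_config()] (staffing anchor), or `NULL`.
#' @return A list of class `scenario_analysis` with elements `fmdb`
#'   (tibble of per-respondent costs and savings by fraction), `localized`
#'   (summaries + percentage decreases) and `national` (per-arm projections).
#' @export
run_scenarios <- function(ledger, wages, macro, n, country,
                          borrow_fractions = c(0.25, 0.5, 0.75),
                          role_substitutions = default_role_substitutions(),
                          national = NULL, base_config = NULL,
                          params = valuation_params()) {
  base <- run_primary_analysis(ledger, wages, macro, n, country,
                               params = params)

  fmdb <- purrr::map_dfr(borrow_fractions, function(f) {
    led_f <- apply_fmdb_borrow(ledger, f, params)
    valued <- value_ledger(led_f, wages, macro, params)
    s_in <- summarize_ledger(valued, country, "inddex24", n[["inddex24"]],
                             params = params)
    s_pa <- summarize_ledger(valued, country, "papi", n[["papi"]],
                             params = params)
    tibble::tibble(
      borrow_fraction = f,
      inddex24_per_respondent = s_in$per_respondent,
      papi_per_respondent = s_pa$per_respondent,
      saving_vs_papi = s_pa$per_respondent - s_in$per_respondent,
      pct_decrease_inddex24 = pct_decrease(
        base$summaries$inddex24$per_respondent, s_in$per_respondent
      )
    )
  })

  led_loc <- apply_localization(ledger, role_substitutions)
  valued_loc <- value_ledger(led_loc, wages, macro, params)
  localized <- purrr::map(
    stats::setNames(c("inddex24", "papi"), c("inddex24", "papi")),
    ~summarize_ledger(valued_loc, country, .x, n[[.x]], params = params)
  )
  localized_pct <- purrr::imap_dbl(
    localized,
    ~pct_decrease(base$summaries[[.y]]$per_respondent, .x$per_respondent)
  )

  national_res <- NULL
  if (!is.null(national)) {
    if (is.null(base_config)) {
      stop("the national scenario needs a base_config staffing anchor")
    }
    national_res <- purrr::map(
      stats::setNames(c("inddex24", "papi"), c("inddex24", "papi")),
      ~project_national(valued_loc, national, base_config(n[[.x]]), country,
                        .x, params)
    )
  }
  structure(
    list(country = country, base = base, fmdb = fmdb, localized = localized,
         localized_pct_decrease = localized_pct, national = national_res),
    class = "scenario_analysis"
  )
}

#' Export analysis results
#'
#' Writes the activity-layout cost report as CSV or aligned text and the
#' whole result set (summaries, differences, respondent costs and the
#' valuation parameters used, for auditability) as machine-readable JSON.
#'
#' @param analysis A `primary_analysis`.
#' @param dir Output directory (created if needed).
#' @param format One or more of `"csv"`, `"json"`, `"text"`.
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(analysis, dir, format = c("csv", "json", "text")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  if ("csv" %in% format) {
    p <- file.path(dir, sprintf("cost_report_%s.csv", analysis$country))
    readr::write_csv(analysis$report, p)
    p2 <- file.path(dir, sprintf("time_nontime_%s.csv", analysis$country))
    readr::write_csv(analysis$time_nontime, p2)
    paths <- c(paths, p, p2)
  }
  if ("text" %in% format) {
    p <- file.path(dir, sprintf("cost_report_%s.txt", analysis$country))
    writeLines(utils::capture.output(print(as.data.frame(analysis$report))),
               p)
    paths <- c(paths, p)
  }
  if ("json" %in% format) {
    p <- file.path(dir, sprintf("results_%s.json", analysis$country))
    out <- list(
      country = analysis$country,
      summaries = purrr::map(analysis$summaries, glance),
      per_respondent_difference = analysis$difference$per_respondent,
      respondent_costs = analysis$respondent_costs,
      valuation_params = unclass(analysis$params_used)
    )
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  invisible(paths)
}
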