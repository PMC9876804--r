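# Aggregation: valued ledger -> reporting surfaces -------------------------

arm_slice <- function(valued, country, modality,
                      shared_allocation = "duplicate") {
  x <- dplyr::filter(valued, .data$country == !!country,
                     .data$modality %in% c(!!modality, "shared"))
  if (shared_allocation == "split") {
    x$cost_usd[x$modality == "shared"] <- x$cost_usd[x$modality == "shared"] / 2
  }
  x
}

#' Summarize a valued ledger for one survey arm
#'
#' Rolls the valued ledger up into the reporting surface for one country,
#' data-collection modality and costing perspective: total cost, cost per
#' respondent, disaggregations by activity and by cost centre, and the split
#' into time (human capital; personnel items) and non-time costs. Items with
#' `modality = "shared"` (inputs used by both arms, e.g. dietary reference
#' data) are charged to the arm per the allocation rule in `params`.
#'
#' @param valued A ledger with a `cost_usd` column (see [value_ledger()]).
#' @param country `"vietnam"` or `"burkina_faso"`.
#' @param modality `"inddex24"` or `"papi"`.
#' @param n_respondents Number of respondents in the arm.
#' @param perspective `"societal"` (all payers) or `"respondent"` (items with
#'   `payer == "respondent"` only).
#' @param params A [valuation_params()] (controls shared-item allocation).
#' @return A `ledger_summary` object.
#' @export
summarize_ledger <- function(valued, country, modality, n_respondents,
                             perspective = c("societal", "respondent"),
                             params = valuation_params()) {
  perspective <- match.arg(perspective)
  stopifnot("cost_usd" %in% names(valued), n_respondents > 0)
  stopifnot(country %in% cost_countries,
            modality %in% c("inddex24", "papi"))
  x <- arm_slice(valued, country, modality, params$shared_allocation)
  if (perspective == "respondent") {
    x <- dplyr::filter(x, !is.na(.data$payer), .data$payer == "respondent")
  }
  if (nrow(x) == 0) {
    warning(sprintf("no items for %s/%s (%s perspective); zero summary",
                    country, modality, perspective))
  }
  by_activity <- x |>
    dplyr::count(activity = factor(.data$activity, cost_activities),
                 wt = .data$cost_usd, name = "cost_usd", .drop = FALSE) |>
    dplyr::mutate(activity = as.character(.data$activity))
  by_centre <- x |>
    dplyr::count(cost_centre = factor(.data$cost_centre, cost_centres),
                 wt = .data$cost_usd, name = "cost_usd", .drop = FALSE) |>
    dplyr::mutate(cost_centre = as.character(.data$cost_centre))
  total <- sum(x$cost_usd)
  time_cost <- sum(x$cost_usd[x$cost_centre == "personnel"])
  structure(
    list(country = country, modality = modality, perspective = perspective,
         n_respondents = n_respondents, total = total,
         per_respondent = total / n_respondents,
         by_activity = by_activity, by_centre = by_centre,
         time_cost = time_cost, nontime_cost = total - time_cost),
    class = "ledger_summary"
  )
}

#' @export
print.ledger_summary <- function(x, ...) {
  cat(sprintf("<ledger_summary> %s / %s (%s perspective)\n",
              x$country, x$modality, x$perspective))
  cat(sprintf("  total: $%s   per respondent (n %d): $%s\n",
              format(round_half_up(x$total), big.mark = " "),
              x$n_respondents,
              format(round_half_up(x$per_respondent), big.mark = " ")))
  cat(sprintf("  time (human capital): $%s   non-time: $%s\n",
              format(round_half_up(x$time_cost), big.mark = " "),
              format(round_half_up(x$nontime_cost), big.mark = " ")))
  invisible(x)
}

#' Broom-style accessors for ledger summaries
#'
#' `tidy()` returns the disaggregations in long form (one row per activity
#' and per cost centre, with cost and share); `glance()` returns a one-row
#' tibble of the headline figures.
#'
#' @param x A `ledger_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.ledger_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$by_activity |>
      dplyr::transmute(axis = "activity", level = .data$activity,
                       cost_usd = .data$cost_usd),
    x$by_centre |>
      dplyr::transmute(axis = "cost_centre", level = .data$cost_centre,
                       cost_usd = .data$cost_usd)
  ) |>
    dplyr::mutate(
      share = if (x$total > 0) .data$cost_usd / x$total else NA_real_,
      country = x$country, modality = x$modality,
      perspective = x$perspective, .before = 1
    )
}

#' @rdname tidy.ledger_summary
#' @export
glance.ledger_summary <- function(x, ...) {
  tibble::tibble(
    country = x$country, modality = x$modality, perspective = x$perspective,
    n_respondents = x$n_respondents, total = x$total,
    per_respondent = x$per_respondent,
    time_cost = x$time_cost, nontime_cost = x$nontime_cost
  )
}

#' Cost per respondent
#'
#' Cost efficiency: total cost divided by the number of respondents, rounded
#' to the nearest dollar (half away from zero) for reporting.
#'
#' @param total Total cost in USD.
#' @param n Number of respondents (> 0).
#' @param round Round to the nearest dollar (default) or return the raw
#'   quotient.
#' @return USD per respondent.
#' @export
#' @examples
#' cost_per_respondent(120483, 147) # 820
cost_per_respondent <- function(total, n, round = TRUE) {
  if (any(n <= 0)) stop("n must be positive")
  out <- total / n
  if (round) round_half_up(out) else out
}

#' Difference between two survey arms
#'
#' Element-wise differences (first arm minus second arm, conventionally
#' INDDEX24 minus PAPI) of activity totals, overall total and cost per
#' respondent. Negative values mean the first arm is cheaper. The
#' per-respondent difference is computed from the unrounded per-respondent
#' values, then rounded.
#'
#' @param a,b `ledger_summary` objects sharing country and perspective.
#' @return A list with `by_activity` (tibble of differences), `total`,
#'   `per_respondent` (rounded) and `per_respondent_raw`.
#' @export
arm_difference <- function(a, b) {
  if (a$country != b$country) stop("summaries are for different countries")
  if (a$perspective != b$perspective) {
    stop("summaries are for different perspectives")
  }
  by_activity <- dplyr::left_join(
    a$by_activity, b$by_activity, by = "activity", suffix = c("_a", "_b")
  ) |>
    dplyr::transmute(activity = .data$activity,
                     difference = .data$cost_usd_a - .data$cost_usd_b)
  raw <- a$per_respondent - b$per_respondent
  list(
    country = a$country, modalities = c(a$modality, b$modality),
    by_activity = by_activity,
    total = a$total - b$total,
    per_respondent = round_half_up(raw),
    per_respondent_raw = raw
  )
}

#' Activity and cost-centre shares of a summary
#'
#' Fraction of the total cost attributable to each activity and each cost
#' centre; shares sum to one along each axis.
#'
#' @param summary A `ledger_summary` with positive total.
#' @return A tibble with `axis`, `level`, `share`.
#' @export
share_report <- function(summary) {
  if (summary$total <= 0) stop("shares undefined for a non-positive total")
  tidy(summary)[, c("axis", "level", "share")]
}

# Report writers ------------------------------------------------------------

#' Two-arm cost report in the published table layout
#'
#' Builds the activity-by-arm cost table (activity rows, INDDEX24 and PAPI
#' columns, their difference, plus total and per-respondent rows) for one
#' country, and the tidy time/non-time by activity data behind the cost
#' figures.
#'
#' @param s_inddex24,s_papi `ledger_summary` objects for the two arms.
#' @return A tibble (one row per activity plus `total` and
#'   `per_respondent` rows; dollar figures rounded for presentation).
#' @export
cost_report <- function(s_inddex24, s_papi) {
  d <- arm_difference(s_inddex24, s_papi)
  body <- dplyr::left_join(
    s_inddex24$by_activity, s_papi$by_activity,
    by = "activity", suffix = c("_inddex24", "_papi")
  ) |>
    dplyr::transmute(
      row = .data$activity,
      inddex24 = round_half_up(.data$cost_usd_inddex24),
      papi = round_half_up(.data$cost_usd_papi),
      difference = round_half_up(.data$cost_usd_inddex24 - .data$cost_usd_papi)
    )
  dplyr::bind_rows(
    body,
    tibble::tibble(row = "total",
                   inddex24 = round_half_up(s_inddex24$total),
                   papi = round_half_up(s_papi$total),
                   difference = round_half_up(s_inddex24$total - s_papi$total)),
    tibble::tibble(row = "per_respondent",
                   inddex24 = round_half_up(s_inddex24$per_respondent),
                   papi = round_half_up(s_papi$per_respondent),
                   difference = d$per_respondent)
  )
}

#' Tidy time versus non-time costs by activity
#'
#' The data behind the human-capital/non-human-capital cost figures: for each
#' arm and activity, the personnel (time) and non-personnel (non-time) cost.
#'
#' @param valued A valued ledger.
#' @param country Country to report.
#' @param params A [valuation_params()].
#' @return A tibble with `modality`, `activity`, `component`, `cost_usd`.
#' @export
time_nontime_report <- function(valued, country, params = valuation_params()) {
  purrr::map_dfr(c("inddex24", "papi"), function(m) {
    arm_slice(valued, country, m, params$shared_allocation) |>
      dplyr::mutate(component = ifelse(.data$cost_centre == "personnel",
                                       "time", "non_time")) |>
      dplyr::count(.data$activity, .data$component, wt = .data$cost_usd,
                   name = "cost_usd") |>
      dplyr::mutate(modality = m, .before = 1)
  })
}

#' Plot a two-arm summary
#'
#' Stacked bars of time (human capital) and non-time cost by activity and
#' arm, in the style of the study's cost figures.
#'
#' @param object A valued ledger.
#' @param country Country to plot.
#' @param params A [valuation_params()].
#' @return A ggplot object.
#' @export
plot_time_nontime <- function(object, country, params = valuation_params()) {
  dat <- time_nontime_report(object, country, params)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$activity, y = .data$cost_usd,
                                    fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~modality) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cost (base-year USD)", fill = NULL)
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.ledger_summary <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$cost_usd)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Cost (base-year USD)",
      title = sprintf("%s / %s (%s perspective)", object$country,
                      object$modality, object$perspective)
    )
}
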