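# Interview time-and-motion analysis ---------------------------------------

timing_segments <- c("pass1", "pass2", "pass3", "nonstd_recipe", "pass4",
                     "menu")

#' Read and write interview timing CSV files
#'
#' Schema: `respondent_id,country,modality,site,pass1,pass2,pass3,
#' nonstd_recipe,pass4,menu,total`. The menu segment (the CAPI app's home
#' screen between passes) exists only for `inddex24` rows; for `papi` rows
#' the field is empty.
#'
#' @param path File path.
#' @param timings Timing tibble to write.
#' @return A tibble of per-respondent, per-segment minutes.
#' @name timing_io
#' @export
read_timings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    respondent_id = readr::col_character(),
    country = readr::col_character(),
    modality = readr::col_character(),
    site = readr::col_character(),
    .default = readr::col_double()
  ), na = "")
}

#' @rdname timing_io
#' @export
write_timings <- function(timings, path) {
  readr::write_csv(timings, path, na = "")
  invisible(timings)
}

#' Check timing records
#'
#' Validates segment non-negativity, the modality rule (no menu time under
#' pen-and-paper) and that the recorded total matches the segment sum within
#' a recording tolerance. Mismatches beyond tolerance are flagged, not
#' corrected.
#'
#' @param timings Timing tibble (see [read_timings()]).
#' @param tolerance Allowed absolute total-vs-segment-sum mismatch, minutes.
#' @return Tibble of violations (`respondent_id`, `problem`); zero rows if
#'   clean.
#' @export
validate_timings <- function(timings, tolerance = 1) {
  segs <- intersect(timing_segments, names(timings))
  seg_mat <- as.matrix(timings[, segs])
  v <- list()
  neg <- which(apply(seg_mat, 1, function(r) any(!is.na(r) & r < 0)))
  for (i in neg) {
    v[[length(v) + 1]] <- tibble::tibble(
      respondent_id = timings$respondent_id[i], problem = "negative segment"
    )
  }
  papi_menu <- which(timings$modality == "papi" & !is.na(timings$menu))
  for (i in papi_menu) {
    v[[length(v) + 1]] <- tibble::tibble(
      respondent_id = timings$respondent_id[i],
      problem = "menu time recorded for a papi interview"
    )
  }
  if ("total" %in% names(timings)) {
    sums <- rowSums(seg_mat, na.rm = TRUE)
    off <- which(abs(sums - timings$total) > tolerance)
    for (i in off) {
      v[[length(v) + 1]] <- tibble::tibble(
        respondent_id = timings$respondent_id[i],
        problem = sprintf("total %.1f differs from segment sum %.1f",
                          timings$total[i], sums[i])
      )
    }
  }
  if (length(v) == 0) {
    tibble::tibble(respondent_id = character(), problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Per-stratum timing summaries
#'
#' Mean and sample (n - 1) standard deviation of each interview segment and
#' of the total, per stratum (country x modality, optionally x site). The SD
#' is `NA` for single-record strata. Empty requested strata are omitted with
#' a warning.
#'
#' @param timings Timing tibble.
#' @param by Stratification columns (default country, modality; add
#'   `"site"` for the urban/rural breakdown).
#' @return A tibble with one row per stratum x segment: `n`, `mean`, `sd`.
#' @export
summarize_timings <- function(timings, by = c("country", "modality")) {
  segs <- c(intersect(timing_segments, names(timings)),
            intersect("total", names(timings)))
  timings |>
    tidyr::pivot_longer(dplyr::all_of(segs), names_to = "segment",
                        values_to = "minutes") |>
    dplyr::filter(!is.na(.data$minutes)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by)), .data$segment) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$minutes),
      sd = ifelse(dplyr::n() >= 2, stats::sd(.data$minutes), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(segment = factor(.data$segment,
                                   c(timing_segments, "total"))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), .data$segment) |>
    dplyr::mutate(segment = as.character(.data$segment))
}

#' Two-sample comparison of interview durations
#'
#' Two-sided two-sample t test of a difference in mean minutes, either from
#' raw per-respondent minutes or from summary statistics (n, mean, sd) per
#' group — the latter because published tables report only summaries. The
#' default flavor is Welch (Satterthwaite degrees of freedom), appropriate
#' when group variances differ; the pooled-variance test is available for
#' sensitivity.
#'
#' @param a,b Numeric vectors of minutes, or lists/one-row data frames with
#'   `n`, `mean`, `sd`.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `difference`, `flavor`.
#' @export
#' @examples
#' compare_groups(list(n = 30, mean = 39, sd = 15),
#'                list(n = 30, mean = 44, sd = 10))
compare_groups <- function(a, b, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  as_summary <- function(x) {
    if (is.numeric(x) && is.null(names(x))) {
      list(n = length(x), mean = mean(x), sd = stats::sd(x))
    } else {
      x <- as.list(x)
      stopifnot(all(c("n", "mean", "sd") %in% names(x)))
      x
    }
  }
  sa <- as_summary(a)
  sb <- as_summary(b)
  if (sa$n < 2 || sb$n < 2) stop("each group needs at least two records")
  va <- sa$sd^2 / sa$n
  vb <- sb$sd^2 / sb$n
  if (flavor == "welch") {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  t <- (sa$mean - sb$mean) / se
  tibble::tibble(
    t = t, df = df, p = 2 * stats::pt(-abs(t), df),
    mean_a = sa$mean, mean_b = sb$mean, difference = sa$mean - sb$mean,
    flavor = flavor
  )
}

#' Person-days by activity from staff time logs
#'
#' Total person-days per activity from daily time-log entries (one row per
#' staff member x day x activity, minutes recorded).
#'
#' @param logs Data frame with `activity` and `minutes` columns.
#' @param params A [valuation_params()] (supplies minutes per person-day).
#' @return A tibble with `activity` and `person_days`.
#' @export
persondays_by_activity <- function(logs, params = valuation_params()) {
  stopifnot(all(c("activity", "minutes") %in% names(logs)))
  logs |>
    dplyr::count(.data$activity, wt = .data$minutes, name = "minutes") |>
    dplyr::mutate(person_days = .data$minutes / params$day_minutes,
                  minutes = NULL)
}

#' Plot timing summaries
#'
#' Mean minutes per segment with +/- one SD bars, by modality.
#'
#' @param summaries Output of [summarize_timings()].
#' @return A ggplot object.
#' @export
plot_timings <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$segment, y = .data$mean,
                               fill = .data$modality)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Minutes per interview", fill = NULL)
}
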