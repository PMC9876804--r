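# Domain vocabulary --------------------------------------------------------

#' Closed vocabularies of the costing model
#'
#' The costing model uses closed enumerations for the survey activities, the
#' cost centres (input categories), the data-collection modalities, the study
#' countries, the personnel locations and the cost-variability classes used by
#' the national-scale scenario. These vectors are the single source of truth;
#' every validator checks against them.
#'
#' @format Character vectors.
#' @name cost_enums
NULL

#' @rdname cost_enums
#' @export
cost_activities <- c(
  "dietary_reference_data_prep", "survey_preparation", "training",
  "survey_execution", "data_entry", "data_cleaning_processing",
  "administration"
)

#' @rdname cost_enums
#' @export
cost_centres <- c(
  "personnel", "facilities", "travel", "transportation", "lodging",
  "per_diem", "equipment", "supplies", "other"
)

#' @rdname cost_enums
#' @export
cost_modalities <- c("inddex24", "papi", "shared")

#' @rdname cost_enums
#' @export
cost_countries <- c("vietnam", "burkina_faso")

#' @rdname cost_enums
#' @export
cost_locations <- c("in_country", "international")

#' @rdname cost_enums
#' @export
cost_variabilities <- c("fixed", "per_respondent", "per_enumerator",
                        "per_hub", "per_month")

#' @rdname cost_enums
#' @export
cost_roles <- c(
  "enumerator", "field_supervisor", "data_entry_clerk", "data_supervisor",
  "translator", "coordinator", "researcher", "lead_researcher",
  "statistician", "administrator", "chef", "technical_advisor"
)

# Default useful lives (years) for capital equipment: food scales 2, tablets
# and computers 3, portable hard drives 4, storage cabinets and standard
# weights 10. Extensible through validate_ledger(allowed_lives = ...).
default_useful_lives <- c(2, 3, 4, 10)

ledger_columns <- c(
  "id", "country", "modality", "activity", "subactivity", "cost_centre",
  "payer", "currency", "year", "amount", "quantity", "is_capital",
  "useful_life_years", "role", "person_minutes", "variability", "location"
)

# Ledger constructor --------------------------------------------------------

#' Build a tidy cost ledger
#'
#' A cost ledger has one row per priced input ("ingredient") of one
#' subactivity: the atom of activity-based costing. Columns follow the ledger
#' CSV schema; missing optional fields are `NA`. The constructor fills
#' defaults, coerces types and orders columns; it does not validate (see
#' [validate_ledger()]).
#'
#' @param items A data frame with at least `country`, `modality`, `activity`,
#'   `cost_centre`, `currency`, `year`, `amount`. Optional columns: `id`,
#'   `subactivity`, `payer`, `quantity` (default 1), `is_capital` (default
#'   `FALSE`), `useful_life_years`, `role`, `person_minutes`, `variability`,
#'   `location` (default `"in_country"` for personnel rows).
#' @return A tibble of class `cost_ledger` with the full column set.
#' @export
#' @examples
#' cost_ledger(data.frame(
#'   country = "vietnam", modality = "inddex24", activity = "training",
#'   cost_centre = "supplies", currency = "USD", year = 2019, amount = 120
#' ))
cost_ledger <- function(items) {
  stopifnot(is.data.frame(items))
  x <- tibble::as_tibble(items)
  defaults <- list(
    id = NA_character_, subactivity = NA_character_, payer = NA_character_,
    quantity = 1, is_capital = FALSE, useful_life_years = NA_real_,
    role = NA_character_, person_minutes = NA_real_,
    variability = NA_character_, location = NA_character_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  x <- dplyr::mutate(
    x,
    id = ifelse(is.na(.data$id), sprintf("item%04d", dplyr::row_number()),
                as.character(.data$id)),
    year = as.integer(.data$year),
    amount = as.numeric(.data$amount),
    quantity = as.numeric(.data$quantity),
    is_capital = as.logical(.data$is_capital),
    useful_life_years = as.numeric(.data$useful_life_years),
    person_minutes = as.numeric(.data$person_minutes),
    location = ifelse(
      is.na(.data$location) & .data$cost_centre == "personnel",
      "in_country", .data$location
    )
  )
  x <- dplyr::select(x, dplyr::all_of(ledger_columns), dplyr::everything())
  class(x) <- c("cost_ledger", class(x))
  x
}

#' Validate a cost ledger
#'
#' Checks every structural invariant of the ledger and reports violations
#' without aborting: the activity/centre/modality/country enums are closed,
#' amounts and quantities are non-negative, capital items carry a useful life
#' from the allowed set, personnel items carry a role and person-minutes, and
#' (when a macro table is supplied) every (currency, year) pair is covered.
#'
#' @param ledger A [cost_ledger()].
#' @param macro Optional macro table (see [macro_table()]); when given,
#'   currency/year coverage is checked.
#' @param allowed_lives Numeric vector of admissible useful lives in years.
#' @return A tibble with one row per violation (`id`, `field`, `problem`);
#'   zero rows iff the ledger is well formed.
#' @export
validate_ledger <- function(ledger, macro = NULL,
                            allowed_lives = default_useful_lives) {
  stopifnot(is.data.frame(ledger))
  v <- list()
  note <- function(id, field, problem) {
    tibble::tibble(id = as.character(id), field = field, problem = problem)
  }
  bad <- function(cond) which(!is.na(cond) & cond)

  chk_enum <- function(field, allowed, allow_na = FALSE) {
    val <- ledger[[field]]
    out <- !(val %in% allowed)
    if (allow_na) out <- out & !is.na(val)
    for (i in which(out)) {
      v[[length(v) + 1]] <<- note(ledger$id[i], field,
                                  sprintf("value '%s' not in allowed set", val[i]))
    }
  }
  chk_enum("country", cost_countries)
  chk_enum("modality", cost_modalities)
  chk_enum("activity", cost_activities)
  chk_enum("cost_centre", cost_centres)
  chk_enum("variability", cost_variabilities, allow_na = TRUE)
  chk_enum("location", cost_locations, allow_na = TRUE)

  for (i in bad(ledger$amount < 0)) {
    v[[length(v) + 1]] <- note(ledger$id[i], "amount", "negative amount")
  }
  for (i in bad(ledger$quantity < 0)) {
    v[[length(v) + 1]] <- note(ledger$id[i], "quantity", "negative quantity")
  }
  for (i in which(ledger$is_capital & is.na(ledger$useful_life_years))) {
    v[[length(v) + 1]] <- note(ledger$id[i], "useful_life_years",
                               "capital item without a useful life")
  }
  for (i in which(ledger$is_capital &
                  !is.na(ledger$useful_life_years) &
                  !(ledger$useful_life_years %in% allowed_lives))) {
    v[[length(v) + 1]] <- note(
      ledger$id[i], "useful_life_years",
      sprintf("useful life %g not in {%s}", ledger$useful_life_years[i],
              paste(allowed_lives, collapse = ","))
    )
  }
  pers <- ledger$cost_centre == "personnel"
  for (i in which(pers & is.na(ledger$role))) {
    v[[length(v) + 1]] <- note(ledger$id[i], "role",
                               "personnel item without a role")
  }
  for (i in which(pers & is.na(ledger$person_minutes))) {
    v[[length(v) + 1]] <- note(ledger$id[i], "person_minutes",
                               "personnel item without person-minutes")
  }
  if (!is.null(macro)) {
    keys <- paste(macro$currency, macro$year)
    miss <- !(paste(ledger$currency, ledger$year) %in% keys)
    for (i in which(miss)) {
      v[[length(v) + 1]] <- note(
        ledger$id[i], "currency",
        sprintf("no macro entry for %s %d", ledger$currency[i], ledger$year[i])
      )
    }
  }
  if (length(v) == 0) {
    tibble::tibble(id = character(), field = character(), problem = character())
  } else {
    dplyr::bind_rows(v)
  }
}

# Wage and macro tables -----------------------------------------------------

#' Construct a role-wage table
#'
#' One row per (role, location) pair giving the wage per person-day in a
#' stated currency and year. Field staff are valued at the wage they actually
#' receive; internationally based staff at salaries of comparable positions.
#'
#' @param wages Data frame with `role`, `location`, `currency`, `year`,
#'   `wage_per_day`.
#' @return A tibble of class `wage_table`.
#' @export
wage_table <- function(wages) {
  x <- tibble::as_tibble(wages)
  req <- c("role", "location", "currency", "year", "wage_per_day")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("wage table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x[, c("role", "location")]) > 0) {
    stop("duplicate (role, location) pair in wage table")
  }
  if (any(x$wage_per_day <= 0)) stop("wages must be positive")
  x$year <- as.integer(x$year)
  class(x) <- c("wage_table", class(x))
  x
}

#' Construct a macro table (GDP deflators and exchange rates)
#'
#' One row per (currency, year) giving the implicit GDP price deflator index
#' and the average exchange rate in units of local currency per US dollar
#' (`fx_per_usd = 1` for USD rows).
#'
#' @param macro Data frame with `currency`, `year`, `deflator`, `fx_per_usd`.
#' @return A tibble of class `macro_table`.
#' @export
macro_table <- function(macro) {
  x <- tibble::as_tibble(macro)
  req <- c("currency", "year", "deflator", "fx_per_usd")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("macro table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$deflator <= 0)) stop("deflator values must be positive")
  if (any(x$fx_per_usd <= 0)) stop("fx values must be positive")
  x$year <- as.integer(x$year)
  class(x) <- c("macro_table", class(x))
  x
}

# CSV interfaces ------------------------------------------------------------

ledger_col_types <- readr::cols(
  id = readr::col_character(),
  country = readr::col_character(),
  modality = readr::col_character(),
  activity = readr::col_character(),
  subactivity = readr::col_character(),
  cost_centre = readr::col_character(),
  payer = readr::col_character(),
  currency = readr::col_character(),
  year = readr::col_integer(),
  amount = readr::col_double(),
  quantity = readr::col_double(),
  is_capital = readr::col_logical(),
  useful_life_years = readr::col_double(),
  role = readr::col_character(),
  person_minutes = readr::col_double(),
  variability = readr::col_character(),
  location = readr::col_character()
)

#' Read and write ledger, wage, macro and timing CSV files
#'
#' The on-disk schemas are plain UTF-8 CSV with a single header row and an
#' empty string for absent optional fields. `read_ledger()` returns a
#' [cost_ledger()]; the other readers return the corresponding tables.
#'
#' @param path File path.
#' @param ledger,wages,macro Objects to write.
#' @return Readers return tibbles; writers return the input invisibly.
#' @name ledger_io
#' @export
read_ledger <- function(path) {
  x <- readr::read_csv(path, col_types = ledger_col_types, na = "")
  cost_ledger(x)
}

#' @rdname ledger_io
#' @export
write_ledger <- function(ledger, path) {
  out <- ledger[, intersect(ledger_columns, names(ledger))]
  readr::write_csv(out, path, na = "")
  invisible(ledger)
}

#' @rdname ledger_io
#' @export
read_wage_table <- function(path) {
  wage_table(readr::read_csv(path, col_types = readr::cols(
    role = readr::col_character(), location = readr::col_character(),
    currency = readr::col_character(), year = readr::col_integer(),
    wage_per_day = readr::col_double()
  ), na = ""))
}

#' @rdname ledger_io
#' @export
write_wage_table <- function(wages, path) {
  readr::write_csv(wages, path, na = "")
  invisible(wages)
}

#' @rdname ledger_io
#' @export
read_macro_table <- function(path) {
  macro_table(readr::read_csv(path, col_types = readr::cols(
    currency = readr::col_character(), year = readr::col_integer(),
    deflator = readr::col_double(), fx_per_usd = readr::col_double()
  ), na = ""))
}

#' @rdname ledger_io
#' @export
write_macro_table <- function(macro, path) {
  readr::write_csv(macro, path, na = "")
  invisible(macro)
}
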