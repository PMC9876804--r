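# shared helpers: tiny hand-built tables used across test files

toy_macro <- function() {
  macro_table(tibble::tribble(
    ~currency, ~year, ~deflator, ~fx_per_usd,
    "USD", 2018L, 110.0, 1,
    "USD", 2019L, 112.2, 1,
    "VND", 2018L, 180.0, 22000,
    "VND", 2019L, 183.6, 23000,
    "XOF", 2018L, 100.0, 560,
    "XOF", 2019L, 100.0, 575
  ))
}

toy_wages <- function() {
  wage_table(tibble::tribble(
    ~role, ~location, ~currency, ~year, ~wage_per_day,
    "enumerator", "in_country", "USD", 2019L, 80,
    "researcher", "in_country", "USD", 2019L, 80,
    "researcher", "international", "USD", 2019L, 400,
    "data_entry_clerk", "in_country", "XOF", 2019L, 46000
  ))
}

# three-item well-formed ledger: one personnel, one capital, one plain item
toy_ledger <- function() {
  cost_ledger(tibble::tibble(
    id = c("p1", "k1", "s1"),
    country = "vietnam",
    modality = c("inddex24", "inddex24", "papi"),
    activity = c("survey_execution", "survey_preparation", "training"),
    subactivity = c("interviews", "tablets", "venue"),
    cost_centre = c("personnel", "equipment", "facilities"),
    payer = "study",
    currency = "USD",
    year = 2019L,
    amount = c(0, 250, 100),
    quantity = c(1, 4, 1),
    is_capital = c(FALSE, TRUE, FALSE),
    useful_life_years = c(NA, 3, NA),
    role = c("enumerator", NA, NA),
    person_minutes = c(480, NA, NA),
    variability = c("per_respondent", "per_enumerator", "fixed"),
    location = c("in_country", NA, NA)
  ))
}

# independent brute-force total: a plain loop over rows, no dplyr
brute_force_total <- function(valued, country, modality,
                              shared = "duplicate") {
  tot <- 0
  for (i in seq_len(nrow(valued))) {
    if (valued$country[i] != country) next
    m <- valued$modality[i]
    if (m == modality) {
      tot <- tot + valued$cost_usd[i]
    } else if (m == "shared") {
      tot <- tot + valued$cost_usd[i] * if (shared == "split") 0.5 else 1
    }
  }
  tot
}
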