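Package: recallcost
Title: Activity-Based Costing of 24-Hour Dietary Recall Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An activity- and ingredients-based costing engine for 24-hour
    dietary recall (24HR) surveys. Represents survey expenditures as a tidy
    cost ledger (one row per priced input of one subactivity), values every
    item in base-year US dollars using GDP-deflator adjustment, average
    exchange rates, equivalent-annual-cost annualization of capital
    equipment and wage-based valuation of personnel and respondent time,
    and rolls the valued ledger up into cost-efficiency summaries (total
    and per-respondent cost, activity, cost-centre and time versus
    non-time disaggregations). Includes a scenario engine for three
    counterfactuals (borrowing dietary reference data, localizing
    international personnel, and projecting to national scale with a
    staffing model), a time-and-motion analysis of interview durations
    with Welch two-sample comparisons, and seeded synthetic-data
    generators so every stage is testable without access to the original
    expenditure records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    generics,
    withr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
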