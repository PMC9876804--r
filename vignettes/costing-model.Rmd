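---
title: "Activity-based costing of 24-hour dietary recall surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based costing of 24-hour dietary recall surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallcost)
```

## The costing model

Collecting individual dietary data by 24-hour recall (24HR) is expensive, and
the cost structure differs sharply between computer-assisted personal
interviewing (CAPI, here the INDDEX24 platform) and traditional pen-and-paper
interviewing (PAPI). `recallcost` implements an activity- and
ingredients-based costing model for such surveys: every expenditure is one
row of a *cost ledger* — one priced input ("ingredient") of one subactivity
of one of seven closed activities (dietary reference data preparation, survey
preparation, training, survey execution, data entry, data cleaning and
processing, administration), classified into one of nine cost centres
(personnel, facilities, travel, transportation, lodging, per diem, equipment,
supplies, other). Costs are taken from a societal perspective: all costs
count regardless of who incurs them, including the respondents' own time. A
respondent-only perspective is available through the `payer` field.

Items used by both survey arms — above all the dietary reference data (food
lists, standard recipes, conversion and density factors, portion-size
estimation methods) — carry `modality = "shared"`. By default each arm is
charged the full shared cost (`shared_allocation = "duplicate"`), matching
how such data serve each modality in full; a 50/50 `"split"` rule is
available for budget-attribution use cases where the double count is not
wanted.

## Valuation rules

Every item is converted to base-year US dollars (default 2019) before
aggregation:

1. **Deflation.** Amounts are moved to base-year prices with the GDP implicit
   price deflator of their own currency:
   $a' = a \cdot d(\text{base})/d(\text{year})$.
2. **Conversion.** Local-currency amounts are then converted at the
   *base-year* average exchange rate, $a'' = a'/\text{fx}$. The order is
   contractual: deflate locally first, convert second; USD amounts are never
   touched by the exchange rate.
3. **Annualization.** Capital equipment (food scales, 2-year useful life;
   tablets and computers, 3 years; portable hard drives, 4 years; storage
   cabinets and standard weights, 10 years) is spread over its useful life
   with the equivalent annual cost $E = K/A$, where the annuity factor is
   $A = (1-(1+r)^{-n})/r$ at discount rate $r$ (default 3 %), and $A = n$
   when $r = 0$. The survey is charged
   $E \times \text{survey\_duration\_months}/12$; the default attributes the
   full annualized year (12 months), since the alternative — prorating by
   field months — would understate equipment tied up by the survey for a
   full procurement cycle. Backup scales and tablets bought against loss or
   damage are part of the recorded quantities.
4. **Personnel time.** Personnel items carry person-minutes and a role; cost
   is $\text{minutes}/480 \times \text{wage}$, with one person-day fixed at
   480 minutes (8 h, configurable) and the per-day wage looked up by (role,
   location) and normalized like any other amount.
5. **Respondent time.** Interview minutes plus about 15 minutes of
   recruitment and consent are valued at the regional minimum monthly wage
   spread over a 168-hour working month (21 days of 8 h):
   $(m + 15) \cdot w/(168 \cdot 60)$. The 168-hour convention was fixed
   after verifying that it reproduces the published participation costs
   ($0.81 and $0.36 per respondent) from the published interview times and
   minimum wages; it is configurable through `valuation_params()`.

Internal arithmetic runs at full precision. Only reports round: totals and
per-respondent costs to the nearest dollar, respondent participation costs to
the cent, always half away from zero. Arm differences are computed from
*unrounded* per-respondent values and rounded last — this is why the Viet Nam
per-respondent difference is $-64$ (from $755.13 - 819.61 = -64.48$) and not
the $-65$ that differencing rounded values would give.

## The tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `base_year` | 2019 | year all costs are expressed in |
| `discount_rate` | 0.03 | annual rate in the annuity factor |
| `day_minutes` | 480 | minutes per person-day |
| `hours_per_month` | 168 | working hours behind a monthly wage |
| `survey_duration_months` | 12 | annualized months charged to the survey |
| `consent_minutes` | 15 | respondent recruitment/consent time |
| `shared_allocation` | duplicate | shared-item charging rule |

## Scenarios

Three counterfactuals are built in:

* **Reference-data borrowing** (`apply_fmdb_borrow()`): a fraction of the
  dietary reference data is borrowed from a shared repository (the Global
  Food Matters Database), so the CAPI arm's reference-data preparation cost
  scales by $1-f$; the PAPI comparison arm is left unchanged. Both the
  monetary amount and the person-minutes of affected items are scaled, so
  the rule is independent of how an item is priced, and borrowing commutes
  with the localization scenario.
* **Personnel localization** (`apply_localization()`): every internationally
  based position is re-priced at the wage of its in-country equivalent;
  person-minutes are unchanged. The substitution map is explicit, and a
  missing substitution for an international role present in the ledger is an
  error rather than a silent carry-over.
* **National scale** (`project_national()`): the validation-scale ledger is
  projected to a national survey through each item's cost-variability class.
  Fixed items carry over; `per_respondent` items scale with effective
  interviews (respondents times one plus the 20 % replicate-recall
  fraction); `per_enumerator` items — tablets, scales — scale with the
  enumerator full-time-equivalent ratio, so equipment is re-derived from the
  staffing model; `per_hub` items scale with the number of subnational
  coordination hubs and `per_month` items with total field months.

The staffing model (`staffing_requirements()`) converts a survey
configuration into full-time equivalents: enumerators from interviews per
enumerator-day (4 at national scale, where teams are experienced and data
collection is the only task) times 22 working days per month times months per
hub; field supervisors at 1 per 6 enumerators; and, for PAPI only, data-entry
clerks keying 8 interviews per day with data supervisors at 1 per 10 clerks.
Electronic capture needs no clerks; one data supervisor per hub performs
ongoing electronic data monitoring. Reported staffing is rounded to the
nearest whole number (not ceiled — a deliberate choice documented here
because budgeting practice often ceils); the scaling ratios inside
`project_national()` use unrounded FTEs so that projecting a survey onto its
own configuration is exactly the identity.

National configurations packaged with the fixtures assume Viet Nam: n 4 376
women, 3 hubs covering the six agro-ecological zones for 2 months each;
Burkina Faso: n 6 500, 4 hubs covering the thirteen regions for 3 months
each. The validation-study anchor uses the same staffing formula with one
hub, one month and an effective throughput of 1.1 interviews per
enumerator-day — validation-study enumerators spent much of each day on
benchmark-related tasks, so their recall throughput was far below a dedicated
national team's.

## The synthetic data

No expenditure records of the underlying studies are public, so the package
generates its own data at two levels.

`study_fixture()` is a *calibrated* deterministic ledger pair per country. It
fixes what is published — arm totals to the dollar ($111 004 / $120 483 in
Viet Nam, $78 105 / $79 456 in Burkina Faso), the reference-data share
(about 37 % / 34 % in Viet Nam), the survey-preparation and administration
shares in Burkina Faso (about 23 % / 20 % / 25 %), personnel shares inside
the published 67–83 % band, the per-respondent costs after localization
($498 / $448 and $456 / $410) and the national-scale totals ($477 267 /
$601 001 and $802 385 / $962 297) — and solves a small allocation for the
remainder: the internationally-priced block is pinned by the localization
outcome, the per-respondent-variable block by the national-scale outcome
(a linear equation in the scaling ratios), and residual blocks absorb the
rest activity by activity. The item level is therefore a synthetic
reconstruction with the published marginals, not the true ledger; green
fixture tests establish that the engine reproduces the published cost
surface from a ledger with that structure, nothing more.

`generate_ledger()` and `generate_timings()` are seeded stochastic
generators for property-style testing: ledgers with exact target activity
and personnel shares and capital items over the standard useful lives;
interview durations drawn from a normal distribution truncated at zero
(log-normal by flag) with the published total-time moments (39 ± 15 and
44 ± 10 minutes in Viet Nam; 47 ± 18 and 50 ± 20 in Burkina Faso) and
Dirichlet-split passes that sum exactly to the total, with the menu segment
only in the CAPI arm. Truncation at zero pulls the realized mean about 0.2
minutes above the nominal mean at the Viet Nam CAPI parameters; tests
allow for this explicitly. The generators do not emulate enumerator
learning effects, site heterogeneity beyond an urban/rural label, or
recording error in the time logs.

## Numerical and design choices

* Rounding is half away from zero everywhere a report rounds; base R's
  round-half-even would differ on exact halves.
* The total-versus-segment-sum recording tolerance for timing records is
  1 minute; mismatches beyond it are flagged, never corrected.
* The two-sample comparison of interview durations defaults to the Welch
  test (the published SDs differ visibly between arms: 15 vs 10 minutes);
  the pooled test is available for sensitivity, and both accept
  summary-statistic input because published tables carry only means and
  SDs. No multiple-testing adjustment is applied across passes.
* Overhead and IRB fees are ordinary ledger items under cost centre
  `other`; the model imposes no overhead rate.
* Equivalent annual cost exceeds the purchase price at a one-year useful
  life with a positive discount rate ($E = K(1+r)$); this is the financing
  cost, not an error, and the invariant tests assert $E \le K$ only from
  two years up.
* The national projection drops capacity-building items (subactivities
  labelled `capacity_building`) unless the configuration retains them,
  reflecting a national team assumed able to run the survey without
  external support.

## A worked example

```{r}
fx <- study_fixture("vietnam")
valued <- value_ledger(fx$ledger, fx$wages, fx$macro)
s_in <- summarize_ledger(valued, "vietnam", "inddex24", 147)
s_pa <- summarize_ledger(valued, "vietnam", "papi", 147)
s_in
arm_difference(s_in, s_pa)$per_respondent
head(tidy(s_in))
```

## Known limitations

The fixture reproduces published marginals, not the unpublished item-level
records, so item-level conclusions (e.g. which subactivity drives a
difference) are only as good as the synthetic allocation. The per-month
scaling of field costs tracks hub-months, not staff-months, and so
understates per-diem growth when staff counts grow faster than the
timeline. Wage tables are user-supplied; the packaged defaults are
synthetic approximations of 2019 conditions. The model contains no
cost-effectiveness (accuracy-adjusted) analysis and no optimization of hub
placement or staffing schedules.
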