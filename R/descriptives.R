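# Cohort description for the deduplicated n-irAE reports: sex, age, year,
# reporter, country, seriousness, outcomes, indications, time to onset.
# Unit of analysis is one deduplicated report; percentages use the
# report-level cohort size as denominator throughout.

occupation_labels <- c(
  MD = "Physician", PH = "Pharmacist", OT = "Other health-professional",
  CN = "Consumer", LW = "Lawyer"
)

outcome_labels <- c(
  DE = "Death", LT = "Life-Threatening",
  HO = "Hospitalization - Initial or Prolonged", DS = "Disability",
  CA = "Congenital Anomaly",
  RI = "Required Intervention to Prevent Permanent Impairment/Damage",
  OT = "Other"
)

country_aliases <- c(
  "US" = "United States of America", "USA" = "United States of America",
  "UNITED STATES" = "United States of America",
  "UNITED STATES OF AMERICA" = "United States of America",
  "JP" = "Japan", "JAPAN" = "Japan",
  "FR" = "France", "FRANCE" = "France",
  "DE" = "Germany", "GERMANY" = "Germany",
  "CN" = "China", "CHINA" = "China",
  "CA" = "Canada", "CANADA" = "Canada",
  "GB" = "United Kingdom", "UK" = "United Kingdom",
  "UNITED KINGDOM" = "United Kingdom",
  "IT" = "Italy", "ITALY" = "Italy",
  "AU" = "Australia", "AUSTRALIA" = "Australia",
  "ES" = "Spain", "SPAIN" = "Spain"
)

normalize_country <- function(x) {
  key <- canonical_term(x)
  out <- unname(country_aliases[key])
  dplyr::coalesce(out, x)
}

#' Convert a reported age to years
#'
#' Unit factors: decades x10, years x1, months /12, weeks /52.143,
#' days /365.25, hours /8766. Results above 120 years are implausible and
#' become missing, as do ages with an absent unit.
#'
#' @param value Nonnegative numeric vector.
#' @param unit Character vector in `{DEC, YR, MON, WK, DY, HR}` or `NA`.
#' @return Numeric vector of ages in years.
#' @examples
#' age_in_years(c(6.7, 780, 67), c("DEC", "MON", "YR"))
#' @export
age_in_years <- function(value, unit) {
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143,
              DY = 1 / 365.25, HR = 1 / 8766)
  out <- value * unname(factor[unit])
  out[!is.na(out) & out > 120] <- NA_real_
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Classify report seriousness
#'
#' A report is serious when it carries at least one regulatory outcome
#' code (death, life-threatening, hospitalization, disability, congenital
#' anomaly, required intervention, other).
#'
#' @param n_outcomes Integer vector: number of outcome records per report.
#' @return `"SERIOUS"` / `"NON_SERIOUS"` character vector.
#' @export
classify_seriousness <- function(n_outcomes) {
  dplyr::if_else(n_outcomes > 0L, "SERIOUS", "NON_SERIOUS")
}

#' Time from first ICI therapy start to event onset
#'
#' Days between the earliest target-ICI therapy start date and the event
#' date, both required at full day precision; partial or missing dates and
#' negative intervals yield `NA`.
#'
#' @param event_dt Raw event date strings (one per report).
#' @param start_dt Raw earliest-start date strings (one per report).
#' @return Integer days, `NA` where undefined.
#' @export
time_to_onset <- function(event_dt, start_dt) {
  ev <- partial_date_full(event_dt)
  st <- partial_date_full(start_dt)
  days <- as.integer(ev - st)
  days[!is.na(days) & days < 0L] <- NA_integer_
  days
}

count_block <- function(labels, total) {
  tibble(label = labels) |>
    filter(!is.na(.data$label)) |>
    count(.data$label, name = "n") |>
    mutate(percent = percent(.data$n, total))
}

#' Summarize the analysis cohort
#'
#' Produces the standard cohort-description blocks for a deduplicated
#' report set: sex, age (years), reporting year, reporter occupation,
#' country, seriousness, outcomes, indications and time to onset. Counts
#' are report-level; every percentage uses the cohort size as denominator.
#' Outcome percentages may sum above 100 because reports carry several
#' outcome codes. Countries and indications are ranked by count
#' descending, ties alphabetical. Quartiles use the Tukey median-of-halves
#' convention (exclusive), an approximation documented in the methods
#' vignette.
#'
#' @param cases Tibble with one row per report and columns `sex`
#'   (`F`/`M`/`UNK`), `age_years`, `year`, `occupation` (raw code or
#'   `NA`), `country`, `n_outcomes`, list-column `outcomes` (codes),
#'   list-column `indications`, `tto_days`.
#' @return A `cohort_summary` object (list of block tibbles) with
#'   [tidy()] and [glance()] methods.
#' @export
summarize_cohort <- function(cases) {
  n <- nrow(cases)
  if (n == 0L) abort("Cohort is empty.")

  sex_lab <- c(F = "Female", M = "Male", UNK = "Not Specified")
  sex <- count_block(unname(sex_lab[cases$sex]), n) |>
    arrange(match(.data$label, sex_lab))

  years <- count_block(as.character(cases$year), n) |> arrange(.data$label)

  occ <- dplyr::coalesce(unname(occupation_labels[cases$occupation]),
                         "Not Specified")
  reporter <- count_block(occ, n) |> arrange(.data$label)

  countries <- count_block(normalize_country(cases$country), n) |>
    arrange(desc(.data$n), .data$label)

  serious <- classify_seriousness(cases$n_outcomes)
  seriousness <- tibble(
    label = c("Serious", "Non-Serious"),
    n = c(sum(serious == "SERIOUS"), sum(serious == "NON_SERIOUS"))
  )
  seriousness$percent <- percent(seriousness$n, nrow(cases))

  out_codes <- unlist(cases$outcomes)
  outcomes <- count_block(unname(outcome_labels[out_codes]), n) |>
    arrange(match(.data$label, outcome_labels))

  indications <- count_block(unlist(cases$indications), n) |>
    arrange(desc(.data$n), .data$label)

  structure(
    list(
      n_reports = n,
      sex = sex,
      age = numeric_block(cases$age_years, n),
      years = years,
      reporter = reporter,
      countries = countries,
      seriousness = seriousness,
      outcomes = outcomes,
      indications = indications,
      tto = numeric_block(cases$tto_days, n)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_reports, "reports\n")
  cat("Serious:", x$seriousness$n[1],
      sprintf("(%.2f%%)\n", x$seriousness$percent[1]))
  cat("Median age:", round_half_up(x$age$median, 2), "years;",
      "median onset:", round_half_up(x$tto$median, 2), "days\n")
  invisible(x)
}

#' Tidy a cohort summary into one long table
#'
#' Stacks every block into a tibble with columns `section`, `label`, `n`,
#' `percent`, `value` — the layout written to `table1.csv`.
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) {
  stat_rows <- function(block, section) {
    tibble(
      section = section,
      label = c("N", "Missing", "Mean", "SD", "Median", "Q1", "Q3",
                "Min", "Max"),
      n = c(block$n, block$missing, rep(NA_integer_, 7)),
      percent = NA_real_,
      value = round_half_up(
        c(NA, NA, block$mean, block$sd, block$median, block$q1, block$q3,
          block$min, block$max), 2)
    )
  }
  count_rows <- function(block, section) {
    block |> mutate(section = section, value = NA_real_) |>
      select("section", "label", "n", "percent", "value")
  }
  bind_rows(
    count_rows(x$sex, "Sex"),
    stat_rows(x$age, "Age (years)"),
    count_rows(x$years, "Reporting year"),
    count_rows(x$reporter, "Reporter"),
    count_rows(x$countries, "Reported countries"),
    count_rows(x$seriousness, "Seriousness"),
    count_rows(x$outcomes, "Outcome"),
    count_rows(x$indications, "Indication"),
    stat_rows(x$tto, "Time to onset (day)")
  )
}

#' One-row overview of a cohort summary
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    n_reports = x$n_reports,
    pct_serious = x$seriousness$percent[1],
    pct_male = x$sex$percent[x$sex$label == "Male"][1],
    median_age = x$age$median,
    median_onset_days = x$tto$median
  )
}
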