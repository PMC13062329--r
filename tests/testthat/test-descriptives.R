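test_that("ages convert to years across reporting units", {
  expect_equal(age_in_years(6.7, "DEC"), 67)
  expect_equal(age_in_years(780, "MON"), 65)
  expect_equal(age_in_years(67, "YR"), 67)
  expect_equal(age_in_years(730.5, "DY"), 2)
  # implausible and unitless ages become missing
  expect_true(is.na(age_in_years(300, "YR")))
  expect_true(is.na(age_in_years(50, NA_character_)))
})

test_that("time to onset needs day precision and nonnegative spans", {
  expect_equal(time_to_onset("20230131", "20230101"), 30L)
  expect_equal(time_to_onset("20230101", "20230101"), 0L)
  expect_true(is.na(time_to_onset("20230131", "202301")))
  expect_true(is.na(time_to_onset("20230101", "20230301")))  # negative
})

test_that("percent rounds half-up to two decimals", {
  expect_equal(percent(10870, 20314), 53.51)
  expect_equal(percent(18533, 20314), 91.23)
  expect_equal(percent(0, 100), 0)
  expect_equal(percent(1, 800), 0.13)  # 0.125 rounds up
  expect_error(percent(1, 0), "positive")
})

test_that("quartiles follow the exclusive median-of-halves convention", {
  expect_equal(unname(tukey_quartiles(c(60, 70))),
               c(60, 65, 70))
  expect_equal(unname(tukey_quartiles(1:5)), c(1.5, 3, 4.5))
  expect_equal(unname(tukey_quartiles(1:8)), c(2.5, 4.5, 6.5))
})

test_that("cohort blocks count reports and percentages coherently", {
  cases <- tibble::tibble(
    sex = c("M", "M", "F", "UNK"),
    age_years = c(60, 70, NA, 50),
    year = c(2024L, 2024L, 2023L, 2024L),
    occupation = c("MD", NA, "CN", "MD"),
    country = c("US", "US", "JAPAN", "FR"),
    outcomes = list(c("HO", "OT"), character(), "DE", "OT"),
    indications = list("Lung cancer", "Lung cancer", "Malignant melanoma",
                       character()),
    tto_days = c(10L, NA, 40L, 20L)
  ) |>
    dplyr::mutate(n_outcomes = lengths(outcomes))

  s <- summarize_cohort(cases)
  expect_equal(s$sex$n[s$sex$label == "Male"], 2L)
  expect_equal(s$sex$percent, c(25, 50, 25))
  expect_equal(sum(s$sex$percent), 100)
  expect_equal(s$age$median, 60)
  expect_equal(s$age$missing, 1L)

  # seriousness: one report with no outcome record
  expect_equal(s$seriousness$n, c(3L, 1L))
  expect_equal(s$seriousness$percent, c(75, 25))

  # multi-outcome reports may push the outcome percent sum past 100
  expect_equal(sum(s$outcomes$n), 4L)
  expect_equal(s$outcomes$percent[s$outcomes$label == "Other"], 50)

  # countries ranked by count, ties alphabetical; aliases normalized
  expect_equal(s$countries$label[1], "United States of America")
  expect_equal(s$countries$label[2:3], c("France", "Japan"))

  tl <- tidy(s)
  expect_true(all(c("section", "label", "n", "percent", "value") %in%
                    names(tl)))
  expect_equal(glance(s)$n_reports, 4L)
})

test_that("generated demographics are recovered at scale", {
  cfg <- synth_config(n_reports = 20000, seed = 99, duplicate_rate = 0,
                      deletion_rate = 0)
  set.seed(cfg$seed)
  u <- synth_universe(cfg)
  mix <- table(u$cases$sex) / nrow(u$cases)
  expect_equal(unname(mix[["M"]]), 0.535, tolerance = 0.02)
  expect_equal(unname(mix[["F"]]), 0.378, tolerance = 0.03)
  expect_equal(mean(u$cases$age_years), 65.1, tolerance = 0.01)
  expect_equal(unname(stats::median(u$cases$tto_days)), 30, tolerance = 0.05)
})
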