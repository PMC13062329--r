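small_cfg <- function(...) {
  synth_config(
    n_reports = 800,
    quarters = c("2024Q1", "2024Q2"),
    seed = 123,
    planted_signals = tibble::tibble(
      exposure = c("PEMBROLIZUMAB", "ATEZOLIZUMAB"),
      partner = c(NA, "PACLITAXEL"),
      event_pt = c("IMMUNE-MEDIATED MYASTHENIA GRAVIS",
                   "NEUROPATHY PERIPHERAL"),
      target_ror = c(20, 10),
      n_exposed = c(120, 60)
    ),
    ...
  )
}

test_that("configuration validation rejects impossible setups", {
  expect_error(synth_config(n_reports = 100, sex_mix = c(M = 0.9, F = 0.9,
                                                         UNK = 0.1)),
               "sum to 1")
  expect_error(
    synth_config(n_reports = 10,
                 planted_signals = tibble::tibble(
                   exposure = "NIVOLUMAB", partner = NA,
                   event_pt = "SEIZURE", target_ror = 5, n_exposed = 50)),
    "more exposed")
  expect_error(
    synth_config(planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = -2, n_exposed = 5)),
    "positive")
})

test_that("expected tables realize the target ROR exactly", {
  cfg <- small_cfg()
  et <- expected_table(cfg, 1)
  expect_equal(et$implied_ror, 20, tolerance = 1e-12)
  # null signal: equal odds in both rows
  cfg_null <- synth_config(
    n_reports = 1000,
    planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = 1, n_exposed = 100))
  et0 <- expected_table(cfg_null, 1)
  expect_equal(et0$a / et0$b, et0$c / et0$d, tolerance = 1e-12)

  # doubling the exposed margin doubles a and b with rates fixed
  cfg2 <- synth_config(
    n_reports = 10000,
    planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = 5, n_exposed = c(500)))
  cfg3 <- synth_config(
    n_reports = 10000,
    planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = 5, n_exposed = c(1000)))
  expect_equal(2 * expected_table(cfg2, 1)$a, expected_table(cfg3, 1)$a)
  expect_equal(2 * expected_table(cfg2, 1)$b, expected_table(cfg3, 1)$b)
})

test_that("the planted cell solves ad/bc = ROR under fixed margins", {
  cfg <- synth_config(
    n_reports = 10000, background_event_rate = 0.01,
    planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = 5, n_exposed = 1000))
  et <- expected_table(cfg, 1)
  # independent numeric root-finder on the same margins
  n_e <- 1000; n_r <- 9000; c0 <- n_r * 0.01; d0 <- n_r - c0
  f <- function(a) (a * d0) / ((n_e - a) * c0) - 5
  a_root <- stats::uniroot(f, c(1e-9, n_e - 1e-9), tol = 1e-12)$root
  expect_equal(et$a, a_root, tolerance = 1e-9)
})

test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synth_generate(cfg, d1)
  synth_generate(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("a noiseless package reads back with zero drops", {
  cfg <- small_cfg(duplicate_rate = 0, deletion_rate = 0,
                   junk_name_rate = 0)
  dir <- withr::local_tempdir()
  synth_generate(cfg, dir)
  for (q in cfg$quarters) {
    qq <- read_quarter(file.path(dir, q), q)
    expect_true(all(qq$log$rows_dropped == 0L))
    expect_true(all(qq$log$coercion_failures == 0L))
    expect_equal(length(qq$deleted_caseids), 0L)
  }
})

test_that("dedup statistics equal the generator ledgers exactly", {
  cfg <- small_cfg(duplicate_rate = 0.15, deletion_rate = 0.05)
  dir <- withr::local_tempdir()
  truth <- synth_generate(cfg, dir)
  quarters <- lapply(cfg$quarters,
                     function(q) read_quarter(file.path(dir, q), q))
  demo <- dplyr::bind_rows(lapply(quarters, `[[`, "demo"))
  deleted <- unique(unlist(lapply(quarters, `[[`, "deleted_caseids")))
  res <- apply_deletions(dedup_reports(demo), deleted)
  expect_equal(res$removed_as_duplicate,
               truth$duplicate_ledger$n_extra_versions)
  expect_equal(res$removed_as_deleted,
               length(truth$deletion_ledger$deleted_caseids))

  # no-noise configuration removes nothing
  cfg0 <- small_cfg(duplicate_rate = 0, deletion_rate = 0)
  dir0 <- withr::local_tempdir()
  synth_generate(cfg0, dir0)
  demo0 <- dplyr::bind_rows(lapply(
    cfg0$quarters, function(q) read_quarter(file.path(dir0, q), q)$demo))
  res0 <- dedup_reports(demo0)
  expect_equal(res0$removed_as_duplicate, 0L)
})

test_that("every variant drug mention normalizes to its ingredient", {
  cfg <- small_cfg(name_variant_rate = 1, junk_name_rate = 0)
  dir <- withr::local_tempdir()
  synth_generate(cfg, dir)
  dict <- load_drug_dictionary()
  drug <- dplyr::bind_rows(lapply(
    cfg$quarters, function(q) read_quarter(file.path(dir, q), q)$drug))
  expect_gt(nrow(drug), 0)
  norm <- normalize_drug_name(drug$drugname, dict)
  expect_false(any(is.na(norm)))
})

test_that("sampled cells track the expected table", {
  cfg <- synth_config(
    n_reports = 50000, background_event_rate = 0.02,
    planted_signals = tibble::tibble(
      exposure = "NIVOLUMAB", partner = NA, event_pt = "SEIZURE",
      target_ror = 5, n_exposed = 2000))
  set.seed(500)
  cells <- dplyr::bind_rows(lapply(1:50, function(i)
    sample_signal_cells(cfg, 1)))
  et <- expected_table(cfg, 1)
  expect_equal(mean(cells$a), et$a, tolerance = 0.1)
  expect_equal(mean(cells$c), et$c, tolerance = 0.05)
  expect_true(all(rowSums(cells) == 50000))
})
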