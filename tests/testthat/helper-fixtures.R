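# Shared in-code fixtures: tiny quarter packages written in the $-dialect
# and a hand-built case table for the screening layer.

write_dollar <- function(df, path) {
  lines <- c(paste(names(df), collapse = "$"),
             apply(df, 1L, function(r) paste(ifelse(is.na(r), "", r),
                                             collapse = "$")))
  writeLines(lines, path)
}

# a 3-case quarter: one unparseable age, one orphan reaction row
fixture_quarter_dir <- function(dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  demo <- data.frame(
    primaryid = c("1001", "1002", "1003"),
    caseid = c("100", "200", "300"),
    fda_dt = c("20240115", "20240210", "20240301"),
    event_dt = c("20231201", "202401", ""),
    sex = c("F", "M", ""),
    age = c("64", "not-a-number", "7.1"),
    age_cod = c("YR", "YR", "DEC"),
    occp_cod = c("MD", "CN", ""),
    reporter_country = c("US", "JP", "FR")
  )
  drug <- data.frame(
    primaryid = c("1001", "1001", "1002", "1003"),
    drug_seq = c("1", "2", "1", "1"),
    role_cod = c("PS", "C", "PS", "PS"),
    drugname = c("KEYTRUDA", "LEVOTHYROXINE", "OPDIVO", "ASPIRIN")
  )
  reac <- data.frame(
    primaryid = c("1001", "1001", "1002", "9999"),
    pt = c("Encephalitis", "Nausea", "Myasthenia gravis", "Headache")
  )
  outc <- data.frame(primaryid = c("1001", "1001", "1002"),
                     outc_cod = c("HO", "OT", "DE"))
  indi <- data.frame(primaryid = c("1001", "1002"),
                     indi_drug_seq = c("1", "1"),
                     indi_pt = c("Lung cancer", "Malignant melanoma"))
  ther <- data.frame(primaryid = c("1001", "1002"),
                     dsg_drug_seq = c("1", "1"),
                     start_dt = c("20231101", "202312"),
                     end_dt = c("20231215", ""))
  write_dollar(demo, file.path(dir, "DEMO.txt"))
  write_dollar(drug, file.path(dir, "DRUG.txt"))
  write_dollar(reac, file.path(dir, "REAC.txt"))
  write_dollar(outc, file.path(dir, "OUTC.txt"))
  write_dollar(indi, file.path(dir, "INDI.txt"))
  write_dollar(ther, file.path(dir, "THER.txt"))
  writeLines(c("777", "888"), file.path(dir, "DELETED.txt"))
  dir
}

# hand-built case table: 10 reports, 3 exposed to drug X, 2 of the exposed
# and 1 unexposed report carry event PT "MYELITIS" -> (a,b,c,d) = (2,1,1,6)
fixture_cases <- function() {
  none <- character()
  cnsii <- "Central nervous system infections and inflammations"
  tibble::tibble(
    primaryid = as.character(1:10),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F", "UNK", "M"),
    age_years = c(40, 70, 55, 66, 30, 80, 61, 44, 59, 72),
    target_icis = list("PEMBROLIZUMAB", "PEMBROLIZUMAB", "PEMBROLIZUMAB",
                       none, none, none, none, none, none, none),
    co_suspect = list(none, "PACLITAXEL", none, none, none, none, none,
                      none, none, none),
    concomitant = rep(list(none), 10),
    target_pts = list("MYELITIS", "MYELITIS", none, "MYELITIS", none,
                      none, none, none, none, none),
    target_hlgts = list(cnsii, cnsii, none, cnsii, none, none, none,
                        none, none, none)
  ) |>
    dplyr::mutate(n_target = lengths(target_icis),
                  n_co_suspect = lengths(co_suspect))
}

# independent closed-form oracle for the ROR interval, assembled through a
# different arithmetic path than compute_ror (odds-of-odds and summed logs)
oracle_ror <- function(a, b, c, d, conf_level = 0.95) {
  or <- (a / c) / (b / d)
  log_or <- log(a) - log(b) - log(c) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ror = or, ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se))
}

# brute-force deduplication oracle: split by caseid, sort each group by
# (padded fda key, numeric primaryid), take the last row
oracle_dedup <- function(demo) {
  groups <- split(seq_len(nrow(demo)), demo$caseid)
  kept <- vapply(groups, function(idx) {
    key <- neurovigil::partial_date_key(demo$fda_dt[idx])
    pid <- as.numeric(demo$primaryid[idx])
    idx[order(key, pid)][length(idx)]
  }, integer(1))
  sort(demo$primaryid[kept])
}
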