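# Synthetic FAERS-dialect quarterly packages with known ground truth.
# Planting model: each signal owns a disjoint block of exposed reports;
# the event probability in the block is raised from the baseline p0 to
#   p1 = ror * p0 / (1 - p0 + ror * p0)
# so that the exposed odds are exactly ror times the background odds and
# the expected 2x2 realizes the target ROR. Reports are then sampled
# independently (the multinomial cell draw over the universe).

#' Synthetic-cohort configuration
#'
#' Defaults encode the study conditions of the analysed cohort: sex mix
#' 53.5/37.8/8.7 (M/F/unknown), age ~ Normal(65.1, 12.76) truncated to
#' [0, 100] years, onset ~ lognormal with median 30 days, ~91% serious
#' reports, outcome-code probabilities matching the cohort table.
#'
#' @param n_reports Number of cases (final versions).
#' @param quarters Quarter labels, e.g. `c("2024Q1", "2024Q2")`.
#' @param seed Integer seed; a fixed seed gives byte-identical packages.
#' @param sex_mix,age_mean_sd Demographic generators.
#' @param duplicate_rate Fraction of cases emitted as 2-3 versions.
#' @param deletion_rate Fraction of cases put on deletion lists.
#' @param name_variant_rate Fraction of drug mentions written as a trade
#'   name, development code or misspelling instead of the generic name.
#' @param background_event_rate Per-PT baseline probability `p0`.
#' @param planted_signals Tibble with columns `exposure` (ICI
#'   ingredient), `partner` (ingredient or `NA`), `event_pt`,
#'   `target_ror`, `n_exposed`.
#' @param background_pts Extra nervous-system PTs reported at baseline
#'   rate by every report.
#' @param serious_rate,outcome_mix Seriousness model: probability of any
#'   outcome record, and per-code probabilities given serious.
#' @param tto_lognormal `c(meanlog, sdlog)` of the onset distribution.
#' @param missing_date_rate Fraction of event/start dates degraded to
#'   month/year precision or blanked.
#' @param co_suspect_rate Fraction of exposed reports carrying an extra
#'   non-ICI co-suspect drug (combination reports).
#' @param concomitant_rate Fraction of reports with a concomitant drug.
#' @param junk_name_rate Fraction of concomitant mentions using an
#'   out-of-dictionary string (exercises the unmapped path).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(
    n_reports = 20000,
    quarters = c("2024Q1", "2024Q2"),
    seed = 20240101,
    sex_mix = c(M = 0.535, F = 0.378, UNK = 0.087),
    age_mean_sd = c(65.1, 12.76),
    duplicate_rate = 0.05,
    deletion_rate = 0.01,
    name_variant_rate = 0.30,
    background_event_rate = 0.02,
    planted_signals = default_planted_signals(),
    background_pts = c("HEADACHE", "DIZZINESS", "TREMOR", "SEIZURE"),
    serious_rate = 0.9123,
    outcome_mix = c(DE = 0.17, LT = 0.0961, HO = 0.5096, DS = 0.0554,
                    CA = 0.0003, RI = 0.0027, OT = 0.7438),
    tto_lognormal = c(meanlog = log(30), sdlog = 1.46),
    missing_date_rate = 0.35,
    co_suspect_rate = 0.30,
    concomitant_rate = 0.40,
    junk_name_rate = 0.05) {
  cfg <- list(
    n_reports = as.integer(n_reports), quarters = quarters,
    seed = as.integer(seed), sex_mix = sex_mix,
    age_mean_sd = age_mean_sd, duplicate_rate = duplicate_rate,
    deletion_rate = deletion_rate, name_variant_rate = name_variant_rate,
    background_event_rate = background_event_rate,
    planted_signals = as_tibble(planted_signals),
    background_pts = toupper(background_pts),
    serious_rate = serious_rate, outcome_mix = outcome_mix,
    tto_lognormal = tto_lognormal,
    missing_date_rate = missing_date_rate,
    co_suspect_rate = co_suspect_rate,
    concomitant_rate = concomitant_rate,
    junk_name_rate = junk_name_rate
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_planted_signals <- function() {
  tibble(
    exposure = c("PEMBROLIZUMAB", "NIVOLUMAB", "ATEZOLIZUMAB",
                 "IPILIMUMAB", "PEMBROLIZUMAB"),
    partner = c(NA, NA, NA, NA, "PACLITAXEL"),
    event_pt = c("IMMUNE-MEDIATED MYASTHENIA GRAVIS",
                 "IMMUNE-MEDIATED ENCEPHALOPATHY",
                 "PARANEOPLASTIC NEUROLOGICAL SYNDROME",
                 "IMMUNE-MEDIATED ENCEPHALITIS",
                 "NEUROPATHY PERIPHERAL"),
    target_ror = c(20, 15, 25, 18, 10),
    n_exposed = c(1500, 1400, 800, 600, 400)
  )
}

validate_synth_config <- function(cfg) {
  probs <- c(cfg$duplicate_rate, cfg$deletion_rate, cfg$name_variant_rate,
             cfg$background_event_rate, cfg$serious_rate,
             cfg$missing_date_rate, cfg$co_suspect_rate,
             cfg$concomitant_rate, cfg$junk_name_rate)
  if (any(probs < 0 | probs > 1)) abort("Rates must lie in [0, 1].")
  if (abs(sum(cfg$sex_mix) - 1) > 1e-8) abort("sex_mix must sum to 1.")
  ps <- cfg$planted_signals
  if (nrow(ps)) {
    stopifnot(all(c("exposure", "partner", "event_pt", "target_ror",
                    "n_exposed") %in% names(ps)))
    if (any(ps$target_ror <= 0)) abort("target_ror must be positive.")
    if (any(ps$n_exposed < 1)) abort("n_exposed must be >= 1.")
    if (sum(ps$n_exposed) > cfg$n_reports) {
      abort("Planted signals require more exposed reports than n_reports.")
    }
    for (i in seq_len(nrow(ps))) plant_probs(cfg, i)  # feasibility
  }
  invisible(cfg)
}

# baseline and planted event probabilities for one signal
plant_probs <- function(config, i) {
  s <- config$planted_signals[i, ]
  p0 <- config$background_event_rate
  p1 <- s$target_ror * p0 / (1 - p0 + s$target_ror * p0)
  if (p1 <= 0 || p1 >= 1 || is.na(p1)) {
    abort(sprintf("Infeasible target ROR for signal %d (%s / %s).",
                  i, s$exposure, s$event_pt))
  }
  c(p0 = p0, p1 = p1)
}

#' Expected 2x2 table for a planted signal
#'
#' The deterministic pre-sampling expectation used for planting: exposed
#' block of size `n_exposed` with event probability `p1`, the remaining
#' reports at baseline `p0`. The implied odds ratio equals the target ROR
#' exactly; `a_int`..`d_int` give the deterministically rounded integer
#' cells recorded in the ground truth.
#'
#' @param config A `synth_config`.
#' @param i Signal row index.
#' @return One-row tibble: `a`, `b`, `c`, `d` (expected, real-valued),
#'   integerized counterparts, and `implied_ror`.
#' @export
expected_table <- function(config, i) {
  stopifnot(inherits(config, "synth_config"),
            i >= 1, i <= nrow(config$planted_signals))
  s <- config$planted_signals[i, ]
  p <- plant_probs(config, i)
  n_exp <- s$n_exposed
  n_rest <- config$n_reports - n_exp
  a <- n_exp * p[["p1"]]
  b <- n_exp - a
  c <- n_rest * p[["p0"]]
  d <- n_rest - c
  tibble(
    exposure = s$exposure, event_pt = s$event_pt,
    a = a, b = b, c = c, d = d,
    a_int = round(a), b_int = round(b), c_int = round(c), d_int = round(d),
    implied_ror = (a * d) / (b * c)
  )
}

#' Sample the realized 2x2 cells of a planted signal
#'
#' Draws one universe's worth of exposure/event assignments for signal
#' `i` (exposed block Bernoulli `p1`, remainder Bernoulli `p0`) and
#' returns the realized cells — the replicate engine used for
#' parameter-recovery studies.
#'
#' @param config A `synth_config`.
#' @param i Signal row index.
#' @return One-row tibble with `a`, `b`, `c`, `d`.
#' @export
sample_signal_cells <- function(config, i) {
  s <- config$planted_signals[i, ]
  p <- plant_probs(config, i)
  n_exp <- s$n_exposed
  n_rest <- config$n_reports - n_exp
  a <- stats::rbinom(1L, n_exp, p[["p1"]])
  c <- stats::rbinom(1L, n_rest, p[["p0"]])
  tibble(a = a, b = n_exp - a, c = c, d = n_rest - c)
}

quarter_bounds <- function(label) {
  y <- as.integer(substr(label, 1, 4))
  q <- as.integer(substr(label, 6, 6))
  start <- as.Date(sprintf("%d-%02d-01", y, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

fmt_dt <- function(d) format(d, "%Y%m%d")

degrade_dates <- function(raw, rate) {
  n <- length(raw)
  u <- stats::runif(n)
  out <- raw
  out[u < rate / 3] <- substr(raw[u < rate / 3], 1, 6)        # month
  i2 <- u >= rate / 3 & u < 2 * rate / 3
  out[i2] <- substr(raw[i2], 1, 4)                            # year
  out[u >= 2 * rate / 3 & u < rate] <- ""                     # absent
  out
}

variant_name <- function(ingredient, dict, use_variant) {
  syn_map <- split(dict$synonym, dict$ingredient)
  out <- ingredient
  for (i in which(use_variant)) {
    alt <- setdiff(syn_map[[ingredient[i]]], ingredient[i])
    if (length(alt)) out[i] <- alt[sample.int(length(alt), 1L)]
  }
  out
}

#' Draw one synthetic universe (single version per case)
#'
#' Generates the per-case truth table and the six record tables before
#' duplicate/deletion noise. Used internally by [synth_generate()];
#' exposed directly so tests can reach the pre-noise ground truth.
#'
#' @param config A `synth_config`; the caller controls the RNG state.
#' @param dict Drug dictionary (defaults to the shipped one).
#' @return List of tibbles: `cases` (truth), `demo`, `drug`, `reac`,
#'   `outc`, `indi`, `ther`.
#' @export
synth_universe <- function(config, dict = load_drug_dictionary()) {
  n <- config$n_reports
  ps <- config$planted_signals
  k <- nrow(ps)

  # exposure blocks: signals first, remainder unexposed background
  block <- rep(0L, n)
  if (k) {
    ends <- cumsum(ps$n_exposed)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (i in seq_len(k)) block[starts[i]:ends[i]] <- i
  }

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  quarter <- sample(config$quarters, n, replace = TRUE)

  sex <- sample(names(config$sex_mix), n, replace = TRUE,
                prob = config$sex_mix)
  age <- stats::rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2])
  while (any(bad <- age < 0 | age > 100)) {
    age[bad] <- stats::rnorm(sum(bad), config$age_mean_sd[1],
                             config$age_mean_sd[2])
  }
  age <- round(age)
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.9, 0.05, 0.05))
  age_val <- dplyr::case_when(
    age_cod == "YR" ~ age,
    age_cod == "DEC" ~ age / 10,
    age_cod == "MON" ~ age * 12
  )

  occp <- sample(c("MD", "PH", "OT", "CN", "LW", ""), n, replace = TRUE,
                 prob = c(0.4323, 0.1812, 0.0998, 0.2752, 0.0005, 0.011))
  country <- sample(
    c("US", "JP", "FR", "DE", "CN", "CA", "GB", "IT", "AU", "ES"),
    n, replace = TRUE,
    prob = c(0.36, 0.22, 0.07, 0.05, 0.04, 0.033, 0.025, 0.023, 0.017,
             0.162))

  # dates: therapy start, onset interval, event, receipt within quarter
  qb <- lapply(config$quarters, quarter_bounds)
  names(qb) <- config$quarters
  fda_date <- as.Date(vapply(quarter, function(q) {
    b <- qb[[q]]
    as.character(b[1] + sample.int(as.integer(b[2] - b[1]) + 1L, 1L) - 1L)
  }, character(1)))
  tto <- as.integer(round(stats::rlnorm(n, config$tto_lognormal[1],
                                        config$tto_lognormal[2])))
  tto <- pmin(tto, 4000L)
  event_date <- fda_date - sample.int(60L, n, replace = TRUE)
  start_date <- event_date - tto

  # events: planted PT per signal (p1 in its block, p0 elsewhere),
  # baseline nervous PTs, plus 1-2 non-nervous decoys per report
  planted_pts <- unique(toupper(ps$event_pt))
  event_flags <- matrix(FALSE, n, length(planted_pts),
                        dimnames = list(NULL, planted_pts))
  for (pt in planted_pts) {
    sig_idx <- which(toupper(ps$event_pt) == pt)
    pr <- rep(config$background_event_rate, n)
    for (i in sig_idx) pr[block == i] <- plant_probs(config, i)[["p1"]]
    event_flags[, pt] <- stats::runif(n) < pr
  }
  bg_pts <- setdiff(config$background_pts, planted_pts)
  bg_flags <- matrix(
    stats::runif(n * length(bg_pts)) < config$background_event_rate,
    n, length(bg_pts), dimnames = list(NULL, bg_pts))
  decoys <- c("NAUSEA", "FATIGUE", "RASH", "DIARRHOEA", "PYREXIA",
              "PNEUMONITIS", "PRURITUS", "ARTHRALGIA")
  decoy1 <- sample(decoys, n, replace = TRUE)
  decoy2 <- ifelse(stats::runif(n) < 0.3, sample(decoys, n, replace = TRUE),
                   NA_character_)

  # drugs
  ici <- ifelse(block > 0L, ps$exposure[pmax(block, 1L)], NA_character_)
  partner <- ifelse(block > 0L, ps$partner[pmax(block, 1L)], NA_character_)
  bg_drugs <- c("METFORMIN", "ASPIRIN", "ATORVASTATIN", "OMEPRAZOLE",
                "FUROSEMIDE", "AMLODIPINE", "GEMCITABINE", "PEMETREXED")
  primary_drug <- ifelse(is.na(ici),
                         sample(bg_drugs, n, replace = TRUE), ici)
  extra_suspect <- is.na(partner) & !is.na(ici) &
    stats::runif(n) < config$co_suspect_rate
  suspect2 <- dplyr::case_when(
    !is.na(partner) ~ partner,
    extra_suspect ~ sample(c("PACLITAXEL", "CARBOPLATIN", "CISPLATIN",
                             "ETOPOSIDE"), n, replace = TRUE),
    TRUE ~ NA_character_
  )
  conc <- ifelse(stats::runif(n) < config$concomitant_rate,
                 sample(c("LEVOTHYROXINE", "PREDNISONE", "DEXAMETHASONE",
                          "PANTOPRAZOLE"), n, replace = TRUE),
                 NA_character_)

  # outcomes
  serious <- stats::runif(n) < config$serious_rate
  outc_list <- lapply(seq_len(n), function(i) {
    if (!serious[i]) return(character())
    codes <- names(config$outcome_mix)[
      stats::runif(length(config$outcome_mix)) < config$outcome_mix]
    if (!length(codes)) codes <- "OT"
    codes
  })

  indications <- sample(
    c("Lung cancer", "Malignant melanoma", "Renal cell carcinoma",
      "Breast cancer", "Hepatocellular carcinoma", "Gastric cancer",
      "Bladder cancer", "Type 2 diabetes mellitus", "Hypertension"),
    n, replace = TRUE,
    prob = c(0.18, 0.17, 0.09, 0.04, 0.03, 0.02, 0.01, 0.23, 0.23))

  cases <- tibble(
    caseid = caseid, quarter = quarter, signal_block = block,
    ici = ici, partner = partner, primary_drug = primary_drug,
    suspect2 = suspect2, concomitant = conc,
    sex = sex, age_years = age, age_value = age_val, age_cod = age_cod,
    occp = occp, country = country,
    fda_date = fda_date, event_date = event_date, start_date = start_date,
    tto_days = tto, serious = serious,
    outcomes = outc_list, indication = indications,
    decoy1 = decoy1, decoy2 = decoy2
  )
  for (pt in colnames(event_flags)) cases[[paste0("ev:", pt)]] <- event_flags[, pt]
  for (pt in colnames(bg_flags)) cases[[paste0("ev:", pt)]] <- bg_flags[, pt]

  list(cases = cases, dict = dict)
}

# expand a universe's cases into record tables for given versions
build_tables <- function(cases, dict, config) {
  n <- nrow(cases)
  ev_cols <- grep("^ev:", names(cases), value = TRUE)

  demo <- tibble(
    primaryid = cases$primaryid, caseid = cases$caseid,
    fda_dt = fmt_dt(cases$fda_date),
    event_dt = degrade_dates(fmt_dt(cases$event_date),
                             config$missing_date_rate),
    sex = cases$sex |> (\(s) ifelse(s == "UNK", "", s))(),
    age = as.character(cases$age_value), age_cod = cases$age_cod,
    occp_cod = cases$occp, reporter_country = cases$country
  )

  mention <- function(ingredient) {
    use_var <- stats::runif(length(ingredient)) < config$name_variant_rate
    variant_name(ingredient, dict, use_var)
  }
  drug_rows <- list(
    tibble(primaryid = cases$primaryid, drug_seq = "1", role_cod = "PS",
           drugname = mention(cases$primary_drug)),
    cases |> filter(!is.na(.data$suspect2)) |>
      transmute(primaryid = .data$primaryid, drug_seq = "2",
                role_cod = "SS", drugname = mention(.data$suspect2)),
    cases |> filter(!is.na(.data$concomitant)) |>
      transmute(
        primaryid = .data$primaryid, drug_seq = "3", role_cod = "C",
        drugname = ifelse(stats::runif(dplyr::n()) < config$junk_name_rate,
                          paste0("UNREGISTERED HERBAL ",
                                 sample.int(99L, dplyr::n(), replace = TRUE)),
                          mention(.data$concomitant)))
  )
  drug <- bind_rows(drug_rows)

  reac_planted <- purrr::map(ev_cols, function(col) {
    tibble(primaryid = cases$primaryid[cases[[col]]],
           pt = pt_title_case(sub("^ev:", "", col)))
  })
  reac <- bind_rows(
    reac_planted,
    tibble(primaryid = cases$primaryid, pt = pt_title_case(cases$decoy1)),
    cases |> filter(!is.na(.data$decoy2)) |>
      transmute(primaryid = .data$primaryid,
                pt = pt_title_case(.data$decoy2))
  )

  outc <- tibble(
    primaryid = rep(cases$primaryid, lengths(cases$outcomes)),
    outc_cod = unlist(cases$outcomes)
  )
  indi <- tibble(primaryid = cases$primaryid, indi_drug_seq = "1",
                 indi_pt = cases$indication)
  ther <- tibble(
    primaryid = cases$primaryid, dsg_drug_seq = "1",
    start_dt = degrade_dates(fmt_dt(cases$start_date),
                             config$missing_date_rate),
    end_dt = degrade_dates(fmt_dt(cases$event_date),
                           config$missing_date_rate)
  )
  list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi,
       ther = ther)
}

# generator PT vocabulary is upper-cased internally; files carry the
# slice's original spelling so the mapper's canonicalization is exercised
pt_title_case <- local({
  cache <- NULL
  function(x) {
    if (is.null(cache)) cache <<- load_meddra_slice()
    i <- match(canonical_term(x), cache$pt_key)
    ifelse(is.na(i), x, cache$pt[i])
  }
})

#' Generate quarterly FAERS-dialect packages with ground truth
#'
#' Draws a universe, adds duplicate case versions and deletion-list
#' entries, and writes per-quarter `DEMO/DRUG/REAC/OUTC/INDI/THER.txt`
#' (`$`-delimited) plus `DELETED.txt`, with rows sorted by `primaryid`
#' for byte determinism, and a `ground_truth.json`.
#'
#' @param config A `synth_config`.
#' @param out_dir Output directory; one subdirectory per quarter.
#' @param dict Drug dictionary.
#' @return The ground-truth list, invisibly: `expected` and `realized`
#'   2x2 per planted signal, duplicate and deletion ledgers.
#' @export
synth_generate <- function(config, out_dir,
                           dict = load_drug_dictionary()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  u <- synth_universe(config, dict)
  cases <- u$cases
  n <- nrow(cases)

  # versions: final version number per case in 1..3
  dup <- stats::runif(n) < config$duplicate_rate
  n_versions <- ifelse(dup, sample(2:3, n, replace = TRUE), 1L)
  cases$final_version <- n_versions
  cases$primaryid <- paste0(sub("^0+", "", cases$caseid), n_versions)

  deleted <- stats::runif(n) < config$deletion_rate
  deleted_caseids <- sort(cases$caseid[deleted])

  # realized 2x2 on the post-dedup, post-deletion universe
  alive <- !deleted
  ps <- config$planted_signals
  # realized cells use the analysis-level exposure definition: all alive
  # reports naming the ICI (and, for combination signals, the partner),
  # not just the signal's own planted block
  realized <- purrr::map(seq_len(nrow(ps)), function(i) {
    ev <- cases[[paste0("ev:", toupper(ps$event_pt[i]))]]
    expo <- !is.na(cases$ici) & cases$ici == ps$exposure[i]
    if (!is.na(ps$partner[i])) {
      expo <- expo & !is.na(cases$suspect2) &
        cases$suspect2 == ps$partner[i]
    }
    tibble(exposure = ps$exposure[i], partner = ps$partner[i],
           event_pt = ps$event_pt[i],
           a = sum(alive & expo & ev), b = sum(alive & expo & !ev),
           c = sum(alive & !expo & ev), d = sum(alive & !expo & !ev))
  }) |> bind_rows()

  # earlier versions: same content, smaller fda_dt (20% exact ties) and
  # smaller version digit; placed in an earlier-or-equal quarter
  qi <- match(cases$quarter, config$quarters)
  extra <- cases |> filter(.data$final_version > 1L)
  extra_versions <- list()
  if (nrow(extra)) {
    for (v in 1:2) {
      sub <- extra |> filter(.data$final_version > v)
      if (!nrow(sub)) next
      tie <- stats::runif(nrow(sub)) < 0.2
      off <- ifelse(tie, 0L, sample.int(180L, nrow(sub), replace = TRUE))
      sub$primaryid <- paste0(sub("^0+", "", sub$caseid), v)
      sub$fda_date <- sub$fda_date - off
      sub$quarter <- config$quarters[
        pmax(1L, match(sub$quarter, config$quarters) -
               as.integer(!tie) * sample(0:1, nrow(sub), replace = TRUE))]
      extra_versions[[v]] <- sub
    }
  }
  all_versions <- bind_rows(cases, bind_rows(extra_versions))

  # emit per quarter
  for (q in config$quarters) {
    qdir <- file.path(out_dir, q)
    dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
    sub <- all_versions |> filter(.data$quarter == q)
    sub <- sub[order(as.numeric(sub$primaryid)), , drop = FALSE]
    tabs <- build_tables(sub, dict, config)
    for (tab in names(tabs)) {
      write_faers_table(tabs[[tab]], file.path(qdir,
                                               paste0(toupper(tab), ".txt")))
    }
    del_q <- if (q == utils::tail(config$quarters, 1L)) {
      deleted_caseids
    } else {
      character()
    }
    writeLines(del_q, file.path(qdir, "DELETED.txt"))
  }

  truth <- list(
    expected = purrr::map(seq_len(nrow(ps)),
                          function(i) expected_table(config, i)) |>
      bind_rows(),
    realized = realized,
    duplicate_ledger = list(
      n_cases_duplicated = sum(dup),
      n_extra_versions = sum(n_versions) - n
    ),
    deletion_ledger = list(deleted_caseids = deleted_caseids),
    n_cases = n,
    quarters = config$quarters,
    seed = config$seed
  )
  jsonlite::write_json(
    truth, file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
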