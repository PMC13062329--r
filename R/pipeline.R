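# Orchestration: ingest -> dedup -> normalize -> map -> descriptives ->
# signal screens, with a run manifest whose conservation identities are
# audited before returning.

#' Assemble the deduplicated case table
#'
#' Binds all quarters, applies case-version deduplication and the unioned
#' deletion lists, then attaches per-report exposure profiles, event
#' profiles, outcomes, indications and time to onset. All reports are
#' retained (ICI-exposed or not) because the unexposed reports form the
#' disproportionality comparator.
#'
#' @param quarters List of `faers_quarter` objects from [read_quarter()].
#' @param dict Drug dictionary.
#' @param slice Terminology slice.
#' @param roles Exposure-defining role codes (default PS/SS).
#' @param target_soc SOC defining the events of interest.
#' @return A tibble with one row per kept report; attribute `counts`
#'   carries the stage-by-stage bookkeeping.
#' @export
assemble_cases <- function(quarters, dict = load_drug_dictionary(),
                           slice = load_meddra_slice(),
                           roles = c("PS", "SS"),
                           target_soc = "Nervous system disorders") {
  stopifnot(length(quarters) > 0)
  demo <- bind_rows(purrr::map(quarters, "demo"))
  deleted <- unique(unlist(purrr::map(quarters, "deleted_caseids")))

  dd <- dedup_reports(demo)
  dd <- apply_deletions(dd, deleted)
  kept <- dd$kept

  pull_kept <- function(tab) {
    bind_rows(purrr::map(quarters, tab)) |>
      filter(.data$primaryid %in% kept$primaryid)
  }
  drug <- pull_kept("drug")
  reac <- pull_kept("reac")
  outc <- pull_kept("outc")
  indi <- pull_kept("indi")
  ther <- pull_kept("ther")

  expo <- exposure_profiles(drug, dict, roles = roles)
  evs <- event_profiles(reac, slice, target_soc = target_soc)

  outc_by <- outc |>
    group_by(.data$primaryid) |>
    summarise(outcomes = list(toupper(.data$outc_cod)), .groups = "drop")
  indi_by <- indi |>
    group_by(.data$primaryid) |>
    summarise(indications = list(unique(.data$indi_pt)), .groups = "drop")

  # earliest target-ICI therapy start per report
  targets <- dict$ingredient[dict$is_target_ici]
  ici_seqs <- drug |>
    mutate(ingredient = normalize_drug_name(.data$drugname, dict)) |>
    filter(toupper(trimws(.data$role_cod)) %in% roles,
           .data$ingredient %in% targets) |>
    distinct(.data$primaryid, .data$drug_seq)
  ici_start <- ther |>
    inner_join(ici_seqs,
               by = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq")) |>
    mutate(start = partial_date_full(.data$start_dt)) |>
    filter(!is.na(.data$start)) |>
    group_by(.data$primaryid) |>
    summarise(first_ici_start = min(.data$start), .groups = "drop")

  cases <- kept |>
    left_join(expo, by = "primaryid") |>
    left_join(evs, by = "primaryid") |>
    left_join(outc_by, by = "primaryid") |>
    left_join(indi_by, by = "primaryid") |>
    left_join(ici_start, by = "primaryid") |>
    mutate(
      target_icis = purrr::map(.data$target_icis, \(x) x %||% character()),
      co_suspect = purrr::map(.data$co_suspect, \(x) x %||% character()),
      concomitant = purrr::map(.data$concomitant, \(x) x %||% character()),
      target_classes = purrr::map(.data$target_classes,
                                  \(x) x %||% character()),
      pts = purrr::map(.data$pts, \(x) x %||% character()),
      target_pts = purrr::map(.data$target_pts, \(x) x %||% character()),
      target_hlgts = purrr::map(.data$target_hlgts, \(x) x %||% character()),
      outcomes = purrr::map(.data$outcomes, \(x) x %||% character()),
      indications = purrr::map(.data$indications, \(x) x %||% character()),
      n_target = dplyr::coalesce(.data$n_target, 0L),
      n_co_suspect = dplyr::coalesce(.data$n_co_suspect, 0L),
      n_target_pts = dplyr::coalesce(.data$n_target_pts, 0L),
      n_unmapped = dplyr::coalesce(.data$n_unmapped, 0L),
      age_years = age_in_years(.data$age, .data$age_cod),
      year = as.integer(substr(.data$fda_dt, 1, 4)),
      occupation = .data$occp_cod,
      country = .data$reporter_country,
      n_outcomes = lengths(.data$outcomes),
      tto_days = time_to_onset(
        .data$event_dt,
        ifelse(is.na(.data$first_ici_start), NA_character_,
               format(.data$first_ici_start, "%Y%m%d")))
    )

  counts <- list(
    reports_in = nrow(demo),
    removed_as_duplicate = dd$removed_as_duplicate,
    removed_as_deleted = dd$removed_as_deleted,
    reports_kept = nrow(kept),
    ici_exposed_reports = sum(cases$n_target > 0L),
    nirae_reports_report_level = sum(cases$n_target > 0L &
                                       cases$n_target_pts > 0L),
    nirae_records_record_level = sum(cases$n_target_pts[
      cases$n_target > 0L]),
    unmapped_pt_records = sum(cases$n_unmapped),
    unnormalized_drug_mentions = sum(dplyr::coalesce(cases$unnormalized,
                                                     0L)),
    table_log = bind_rows(purrr::map(quarters, "log"))
  )
  attr(cases, "counts") <- counts
  cases
}

discover_combinations <- function(cases, min_pair_n = 3L) {
  exposed <- cases |> filter(.data$n_target > 0L)
  if (!nrow(exposed)) return(tibble(ici = character(), partner = character()))
  pairs <- purrr::map2(
    exposed$target_icis,
    purrr::pmap(list(exposed$target_icis, exposed$co_suspect,
                     exposed$concomitant),
                function(t, cs, cm) unique(c(t, cs, cm))),
    function(icis, all_drugs) {
      partners <- setdiff(all_drugs[!startsWith(all_drugs, "RAW:")], NULL)
      if (length(icis) == 0L) return(NULL)
      expand.grid(ici = icis, partner = partners,
                  stringsAsFactors = FALSE)
    })
  bind_rows(pairs) |>
    filter(.data$ici != .data$partner) |>
    count(.data$ici, .data$partner, name = "n_pair") |>
    filter(.data$n_pair >= min_pair_n)
}

#' Run the full analysis pipeline
#'
#' Reads every quarter under `input_dir` (one subdirectory per quarter),
#' assembles the deduplicated case table, writes the cohort description
#' (`table1.csv`) for the ICI-exposed nervous-system-event cohort, and
#' the five signal tables (`signals_pt.csv`, `signals_hlgt.csv`,
#' `signals_stratified.csv`, `signals_sensitivity.csv`,
#' `signals_combination.csv`) plus `manifest.json`. Outputs are
#' deterministic for identical inputs and configuration; conservation
#' identities are audited before returning.
#'
#' @param input_dir Directory of quarterly packages.
#' @param out_dir Output directory (created if needed).
#' @param dict_path,slice_path Optional dictionary/slice overrides.
#' @param roles Exposure role codes.
#' @param partner_roles Profile sets supplying combination partners.
#' @param stratify Stratification dimensions to run (subset of
#'   `c("sex", "age")`, or `"none"`).
#' @param top_k Ranked signals kept in the selection column.
#' @param min_cases Signal criterion case minimum.
#' @param min_pair_n Minimum co-occurrence count for a combination pair
#'   to be screened.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         dict_path = NULL, slice_path = NULL,
                         roles = c("PS", "SS"),
                         partner_roles = c("co_suspect", "concomitant",
                                           "target_icis"),
                         stratify = c("sex", "age"),
                         top_k = 50L, min_cases = 3L, min_pair_n = 3L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dict <- load_drug_dictionary(dict_path)
  slice <- load_meddra_slice(slice_path)

  qdirs <- sort(list.dirs(input_dir, recursive = FALSE))
  if (!length(qdirs)) abort(paste("No quarterly packages under", input_dir))
  quarters <- purrr::map(qdirs, \(d) read_quarter(d, basename(d)))

  cases <- assemble_cases(quarters, dict, slice, roles = roles)
  counts <- attr(cases, "counts")

  drugs_present <- sort(unique(unlist(cases$target_icis)))
  cohort <- cases |>
    filter(.data$n_target > 0L, .data$n_target_pts > 0L)
  if (nrow(cohort)) {
    table1 <- tidy(summarize_cohort(cohort))
    write_table(table1, file.path(out_dir, "table1.csv"))
  }

  exposures <- c("any_ici", drugs_present)
  pt_signals <- signal_screen(cases, exposures, level = "pt",
                              min_cases = min_cases)
  pt_signals$selected_rank <- NA_integer_
  sel <- rank_and_select(pt_signals |> filter(.data$exposure == "any_ici"),
                         top_k)
  pt_signals$selected_rank[match(
    paste(sel$exposure, sel$event),
    paste(pt_signals$exposure, pt_signals$event))] <- seq_len(nrow(sel))
  write_table(pt_signals, file.path(out_dir, "signals_pt.csv"))

  hlgt_signals <- signal_screen(cases, exposures, level = "hlgt",
                                min_cases = min_cases)
  write_table(hlgt_signals, file.path(out_dir, "signals_hlgt.csv"))

  strat <- tibble()
  if (!identical(stratify, "none") && length(drugs_present)) {
    strat <- bind_rows(purrr::map(intersect(stratify, c("sex", "age")),
      function(dim) {
        stratified_screen(cases, drugs_present, by = dim, level = "pt",
                          min_cases = min_cases) |>
          mutate(dimension = dim, .before = 1L)
      }))
  }
  write_table(strat, file.path(out_dir, "signals_stratified.csv"))

  mono <- bind_rows(purrr::map(drugs_present, function(dr) {
    monotherapy_screen(cases, dr, level = "pt", min_cases = min_cases)
  }))
  write_table(mono, file.path(out_dir, "signals_sensitivity.csv"))

  pairs <- discover_combinations(cases, min_pair_n)
  combo <- bind_rows(purrr::pmap(pairs, function(ici, partner, n_pair) {
    combination_screen(cases, ici, partner, partner_from = partner_roles,
                       level = "pt", min_cases = min_cases)
  }))
  write_table(combo, file.path(out_dir, "signals_combination.csv"))

  manifest <- list(
    counts = counts[setdiff(names(counts), "table_log")],
    table_log = counts$table_log,
    quarters = purrr::map_chr(quarters, "quarter"),
    config = list(roles = roles, partner_roles = partner_roles,
                  stratify = stratify, top_k = top_k,
                  min_cases = min_cases, min_pair_n = min_pair_n,
                  target_soc = "Nervous system disorders",
                  slice_version = attr(slice, "version_label")),
    n_tests = list(pt = nrow(pt_signals), hlgt = nrow(hlgt_signals),
                   stratified = nrow(strat), sensitivity = nrow(mono),
                   combination = nrow(combo))
  )
  audit_manifest(manifest, cases)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# conservation identities; violation is a defect, so abort
audit_manifest <- function(manifest, cases) {
  cts <- manifest$counts
  if (cts$reports_in - cts$removed_as_duplicate - cts$removed_as_deleted !=
      cts$reports_kept) {
    abort("Audit failure: dedup counts do not conserve report totals.")
  }
  if (cts$reports_kept != nrow(cases)) {
    abort("Audit failure: case table size differs from kept reports.")
  }
  lg <- manifest$table_log
  if (nrow(lg) && any(lg$rows_in != lg$rows_kept + lg$rows_dropped)) {
    abort("Audit failure: per-table row conservation violated.")
  }
  invisible(TRUE)
}
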