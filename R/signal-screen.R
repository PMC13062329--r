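# Screening layer: sweeps exposure definitions (per-drug, pooled class,
# stratified, monotherapy-restricted, combination) over all observed
# events at PT or HLGT level, building one 2x2 per (exposure, event) pair
# against the full deduplicated universe.

event_long <- function(cases, level = c("pt", "hlgt")) {
  level <- match.arg(level)
  col <- if (level == "pt") "target_pts" else "target_hlgts"
  tibble(primaryid = rep(cases$primaryid, lengths(cases[[col]])),
         event = unlist(cases[[col]], use.names = FALSE)) |>
    distinct()
}

has_ingredient <- function(list_col, ingredient) {
  vapply(list_col, function(x) ingredient %in% x, logical(1))
}

screen_cells <- function(cases, exposed, level, events = NULL) {
  ev <- event_long(cases, level)
  totals <- ev |> count(.data$event, name = "n_event")
  in_exposed <- ev$primaryid %in% cases$primaryid[exposed]
  a_tbl <- ev[in_exposed, ] |> count(.data$event, name = "a")
  out <- totals |>
    left_join(a_tbl, by = "event") |>
    mutate(a = dplyr::coalesce(.data$a, 0L))
  if (!is.null(events)) {
    out <- out |>
      full_join(tibble(event = events), by = "event") |>
      mutate(a = dplyr::coalesce(.data$a, 0L),
             n_event = dplyr::coalesce(.data$n_event, 0L)) |>
      filter(.data$event %in% events)
  }
  n_exp <- sum(exposed)
  n_all <- nrow(cases)
  out |>
    mutate(b = n_exp - .data$a,
           c = .data$n_event - .data$a,
           d = n_all - n_exp - .data$c) |>
    select("event", "a", "b", "c", "d")
}

new_signal_table <- function(x) {
  structure(x, class = c("signal_table", class(x)))
}

#' Disproportionality screen at PT or HLGT level
#'
#' For each requested exposure (a single ICI ingredient, or `"any_ici"`
#' for the pooled class) and every event observed in the universe at the
#' requested hierarchy level, builds the 2x2 against all other reports
#' and computes the ROR. Non-signal rows are retained and flagged.
#'
#' @param cases Assembled case table (see [assemble_cases()]).
#' @param exposures Character vector of target ingredients and/or
#'   `"any_ici"`.
#' @param level `"pt"` or `"hlgt"`.
#' @param events Optional restriction of the event vocabulary.
#' @param conf_level,min_cases Passed to [compute_ror()].
#' @return A `signal_table` tibble: `exposure`, `level`, `stratum`,
#'   `event`, the four cells, `ror`, `ci_low`, `ci_high`, `signal`.
#' @export
signal_screen <- function(cases, exposures = "any_ici",
                          level = c("pt", "hlgt"), events = NULL,
                          conf_level = 0.95, min_cases = 3L) {
  level <- match.arg(level)
  rows <- purrr::map(exposures, function(expo) {
    exposed <- if (identical(expo, "any_ici")) {
      cases$n_target > 0L
    } else {
      has_ingredient(cases$target_icis, expo)
    }
    screen_cells(cases, exposed, level, events) |>
      mutate(exposure = expo, level = level, stratum = "overall",
             .before = 1L)
  })
  new_signal_table(compute_ror(bind_rows(rows), conf_level = conf_level,
                               min_cases = min_cases))
}

age_band <- function(age_years, bands = c(45, 65),
                     labels = c("young", "middle", "elderly")) {
  stopifnot(length(bands) + 1L == length(labels), !is.unsorted(bands))
  as.character(cut(age_years, breaks = c(-Inf, bands, Inf),
                   labels = labels, right = FALSE))
}

#' Stratified disproportionality screen
#'
#' Re-runs [signal_screen()] within each stratum's sub-universe. Strata:
#' sex (`F`/`M`) or age bands (default young `<45`, middle `45-64`,
#' elderly `>=65`). Reports with a missing stratum value are excluded
#' from that dimension.
#'
#' @inheritParams signal_screen
#' @param by `"sex"` or `"age"`.
#' @param bands Age cut points (lower edges of the upper bands).
#' @return A `signal_table` with one block per stratum.
#' @export
stratified_screen <- function(cases, exposures = "any_ici",
                              by = c("sex", "age"), level = c("pt", "hlgt"),
                              bands = c(45, 65), events = NULL,
                              conf_level = 0.95, min_cases = 3L) {
  by <- match.arg(by)
  level <- match.arg(level)
  stratum <- switch(by,
    sex = dplyr::if_else(cases$sex %in% c("F", "M"), cases$sex,
                         NA_character_),
    age = age_band(cases$age_years, bands)
  )
  out <- purrr::map(sort(unique(stratum[!is.na(stratum)])), function(s) {
    sub <- cases[!is.na(stratum) & stratum == s, , drop = FALSE]
    signal_screen(sub, exposures, level, events, conf_level, min_cases) |>
      mutate(stratum = s)
  })
  new_signal_table(bind_rows(out))
}

#' Monotherapy sensitivity screen
#'
#' Restricts the exposed set to reports where the drug is the only target
#' ICI and no other suspect drug is present; the comparator is every
#' non-exposed report in the universe (combination reports included).
#'
#' @inheritParams signal_screen
#' @param drug A single target ICI ingredient.
#' @return A `signal_table` with `stratum = "monotherapy"`.
#' @export
monotherapy_screen <- function(cases, drug, level = c("pt", "hlgt"),
                               events = NULL, conf_level = 0.95,
                               min_cases = 3L) {
  level <- match.arg(level)
  stopifnot(drug %in% target_ici_ingredients())
  exposed <- cases$n_target == 1L & cases$n_co_suspect == 0L &
    has_ingredient(cases$target_icis, drug)
  out <- screen_cells(cases, exposed, level, events) |>
    mutate(exposure = drug, level = level, stratum = "monotherapy",
           .before = 1L)
  new_signal_table(compute_ror(out, conf_level = conf_level,
                               min_cases = min_cases))
}

#' Combination-therapy screen
#'
#' Exposure is a report naming the ICI as a suspect drug together with
#' the partner among its partner-role ingredients (co-suspect or
#' concomitant by default); the comparator is every other report.
#'
#' @inheritParams signal_screen
#' @param ici Target ICI ingredient.
#' @param partner Partner ingredient (standardized name).
#' @param partner_from Which profile sets can supply the partner;
#'   `"target_icis"` admits dual-ICI pairs (e.g. a PD-1 inhibitor
#'   combined with a CTLA-4 inhibitor, both suspect drugs).
#' @return A `signal_table` with a `partner` column, mirroring the
#'   combination-table layout (`event`, `a`, `ci_low`).
#' @export
combination_screen <- function(cases, ici, partner,
                               partner_from = c("co_suspect", "concomitant"),
                               level = c("pt", "hlgt"), events = NULL,
                               conf_level = 0.95, min_cases = 3L) {
  level <- match.arg(level)
  stopifnot(ici %in% target_ici_ingredients())
  partner_from <- match.arg(partner_from,
                            c("co_suspect", "concomitant", "target_icis"),
                            several.ok = TRUE)
  if (partner %in% target_ici_ingredients() &&
      !"target_icis" %in% partner_from) {
    partner_from <- c(partner_from, "target_icis")
  }
  has_partner <- rep(FALSE, nrow(cases))
  for (col in partner_from) {
    has_partner <- has_partner | has_ingredient(cases[[col]], partner)
  }
  exposed <- has_ingredient(cases$target_icis, ici) & has_partner
  if (!any(exposed)) {
    return(new_signal_table(compute_ror(tibble(
      exposure = character(), partner = character(), level = character(),
      stratum = character(), event = character(),
      a = integer(), b = integer(), c = integer(), d = integer()
    ))))
  }
  out <- screen_cells(cases, exposed, level, events) |>
    mutate(exposure = ici, partner = partner, level = level,
           stratum = "combination", .before = 1L)
  new_signal_table(compute_ror(out, conf_level = conf_level,
                               min_cases = min_cases))
}

#' Forest-style plot of a signal table
#'
#' Plots each event's ROR (log scale) with its confidence interval,
#' facetted by exposure, signals filled.
#'
#' @param object A `signal_table`.
#' @param top Plot only the `top` rows by `ci_low` (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_table
#' @export
autoplot.signal_table <- function(object, top = 30, ...) {
  df <- object |>
    filter(!.data$undefined) |>
    arrange(desc(.data$ci_low)) |>
    slice_head(n = top) |>
    mutate(event = stats::reorder(.data$event, .data$ci_low))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$signal), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~exposure, scales = "free_y") +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Signal") +
    ggplot2::theme_minimal()
}
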