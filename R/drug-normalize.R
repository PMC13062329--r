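# Verbatim drug strings -> standardized ingredients via an exact-match
# synonym dictionary, after canonicalization (upper-case, whitespace
# collapse, trailing dose/form token stripping). No fuzzy matching.

#' The ten target immune checkpoint inhibitors
#' @return Character vector of standardized ingredient names.
#' @export
target_ici_ingredients <- function() {
  c("PEMBROLIZUMAB", "NIVOLUMAB", "TORIPALIMAB", "TISLELIZUMAB",
    "CEMIPLIMAB", "DOSTARLIMAB", "ATEZOLIZUMAB", "AVELUMAB",
    "DURVALUMAB", "IPILIMUMAB")
}

# fixed, versioned list of trailing dose/form tokens stripped before
# lookup; unknown tokens are never stripped
dose_form_tokens <- c(
  "MG", "MCG", "G", "ML", "MG/ML", "TABLET", "TABLETS", "TAB", "CAPSULE",
  "CAPSULES", "CAP", "INJECTION", "INJ", "SOLUTION", "SOLN", "INFUSION",
  "CONCENTRATE", "ORAL", "IV", "INTRAVENOUS"
)

canonical_drug <- function(raw) {
  x <- canonical_term(raw)
  strip_one <- function(s) {
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1L &&
           (toks[length(toks)] %in% dose_form_tokens ||
            grepl("^[0-9.]+$", toks[length(toks)]))) {
      toks <- toks[-length(toks)]
    }
    paste(toks, collapse = " ")
  }
  vapply(x, strip_one, character(1), USE.NAMES = FALSE)
}

#' Load a drug synonym dictionary
#'
#' Four-column CSV (`synonym`, `ingredient`, `is_target_ici`, `ici_class`).
#' The package ships a license-free synthetic dictionary slice covering the
#' ten target ICIs (generic names, major trade names, development codes,
#' common misspellings) and the frequent combination partners.
#'
#' @param path CSV path; default is the shipped dictionary.
#' @return A `drug_dictionary` tibble with canonicalized synonym keys.
#' @export
load_drug_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_dictionary.csv",
                                package = "neurovigil")
  dict <- readr::read_csv(path, col_types = "cclc", na = "",
                          progress = FALSE) |>
    mutate(
      synonym = canonical_term(.data$synonym),
      ingredient = canonical_term(.data$ingredient),
      ici_class = toupper(.data$ici_class)
    )
  if (anyDuplicated(dict$synonym)) {
    abort("Drug dictionary has duplicate synonym keys after canonicalization.")
  }
  targets <- dict |> filter(.data$is_target_ici)
  missing <- setdiff(target_ici_ingredients(), unique(targets$ingredient))
  if (length(missing)) {
    abort(paste("Drug dictionary lacks synonyms for target ICI(s):",
                paste(missing, collapse = ", ")))
  }
  bad_class <- targets |> filter(!.data$ici_class %in% c("PD1", "PDL1", "CTLA4"))
  if (nrow(bad_class)) {
    abort("Every target ICI synonym needs ici_class in {PD1, PDL1, CTLA4}.")
  }
  structure(dict, class = c("drug_dictionary", class(dict)))
}

#' Normalize a verbatim drug name
#'
#' Canonicalizes (upper-case, trim, collapse whitespace, strip trailing
#' dose/form tokens) then looks the string up in the dictionary; no match
#' yields `NA`.
#'
#' @param raw Character vector of verbatim drug strings.
#' @param dict A [load_drug_dictionary()] table.
#' @return Character vector of ingredients (`NA` where unmatched).
#' @examples
#' dict <- load_drug_dictionary()
#' normalize_drug_name(c("Keytruda", "  nivolumab 240 MG ", "vitamin Q"), dict)
#' @export
normalize_drug_name <- function(raw, dict) {
  key <- canonical_drug(raw)
  dict$ingredient[match(key, dict$synonym)]
}

#' Per-report exposure profiles
#'
#' Classifies every report's drug mentions: target ICIs are collected from
#' suspect roles only (`roles`, default PS/SS); other normalized suspect
#' ingredients become co-suspects; normalized concomitant/interacting
#' ingredients become concomitants. Unnormalizable names are retained
#' verbatim with a `RAW:` prefix so combination analyses do not silently
#' lose partners.
#'
#' @param drug Tibble of drug records (`primaryid`, `drug_seq`, `role_cod`,
#'   `drugname`).
#' @param dict Drug dictionary.
#' @param roles Role codes that qualify a drug as exposure-defining
#'   (default `c("PS", "SS")`).
#' @return Tibble with one row per `primaryid`: list-columns `target_icis`,
#'   `target_classes`, `co_suspect`, `concomitant`, plus `n_target` and
#'   `n_co_suspect` counts and an `unnormalized` counter.
#' @export
exposure_profiles <- function(drug, dict, roles = c("PS", "SS")) {
  stopifnot(inherits(dict, "drug_dictionary"))
  targets <- dict |> filter(.data$is_target_ici)
  d <- drug |>
    mutate(
      role_cod = toupper(trimws(.data$role_cod)),
      ingredient = normalize_drug_name(.data$drugname, dict)
    ) |>
    mutate(
      is_target = !is.na(.data$ingredient) &
        .data$ingredient %in% unique(targets$ingredient),
      label = dplyr::if_else(is.na(.data$ingredient),
                             paste0("RAW:", canonical_drug(.data$drugname)),
                             .data$ingredient),
      suspect = .data$role_cod %in% roles
    )
  class_of <- targets |> distinct(.data$ingredient, .data$ici_class)
  d |>
    group_by(.data$primaryid) |>
    summarise(
      target_icis = list(sort(unique(.data$ingredient[.data$is_target & .data$suspect]))),
      co_suspect = list(sort(unique(.data$label[.data$suspect & !(.data$is_target & .data$suspect)]))),
      concomitant = list(sort(unique(.data$label[!.data$suspect]))),
      unnormalized = sum(is.na(.data$ingredient)),
      .groups = "drop"
    ) |>
    mutate(
      target_classes = purrr::map(.data$target_icis, function(ing) {
        sort(unique(class_of$ici_class[match(ing, class_of$ingredient)]))
      }),
      n_target = lengths(.data$target_icis),
      n_co_suspect = lengths(.data$co_suspect)
    )
}

#' Is a report ICI monotherapy?
#'
#' A report is monotherapy when it names exactly one target ICI and no
#' other suspect drug; concomitant drugs are ignored. Errors on reports
#' with no target ICI, for which the question is undefined.
#'
#' @param profiles Rows of [exposure_profiles()] output.
#' @return Logical vector.
#' @export
is_monotherapy <- function(profiles) {
  if (any(profiles$n_target == 0L)) {
    abort("is_monotherapy() is undefined for reports without a target ICI.")
  }
  profiles$n_target == 1L & profiles$n_co_suspect == 0L
}
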