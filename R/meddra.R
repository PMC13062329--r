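# Reaction preferred terms -> HLGT/SOC through a terminology slice with a
# single primary path per PT (no multi-axiality). Lookup is exact on the
# canonicalized term; unmapped PTs are counted, never guessed.

#' Load a MedDRA-style terminology slice
#'
#' Three-column CSV (`pt`, `hlgt`, `soc`) giving one primary HLGT and SOC
#' per preferred term. The shipped slice is a license-free synthetic
#' stand-in for the licensed dictionary: it covers the nervous-system PTs
#' the analyses use plus non-nervous decoys.
#'
#' @param path CSV path; default is the shipped slice.
#' @param version_label Version tag recorded in manifests.
#' @return A `meddra_slice` tibble with canonicalized `pt_key`.
#' @export
load_meddra_slice <- function(path = NULL, version_label = "synthetic-slice") {
  path <- path %||% system.file("extdata", "meddra_slice.csv",
                                package = "neurovigil")
  slice <- readr::read_csv(path, col_types = "ccc", progress = FALSE) |>
    mutate(pt_key = canonical_term(.data$pt))
  if (anyDuplicated(slice$pt_key)) {
    abort("Terminology slice must have one primary path per PT.")
  }
  attr(slice, "version_label") <- version_label
  structure(slice, class = c("meddra_slice", class(slice)))
}

#' Look up the hierarchy of preferred terms
#'
#' @param pt Character vector of PT strings (any case/spacing).
#' @param slice A [load_meddra_slice()] table.
#' @return Tibble with `pt` (canonical), `hlgt`, `soc`; `NA` rows for
#'   unmapped terms.
#' @examples
#' slice <- load_meddra_slice()
#' map_pt(c("Myasthenia gravis", "NAUSEA", "Zzz unknown"), slice)
#' @export
map_pt <- function(pt, slice) {
  stopifnot(inherits(slice, "meddra_slice"))
  i <- match(canonical_term(pt), slice$pt_key)
  tibble(
    pt = slice$pt_key[i],
    hlgt = slice$hlgt[i],
    soc = slice$soc[i]
  )
}

#' Per-report event profiles
#'
#' Collapses duplicate identical PTs within a report, maps each distinct
#' PT through the slice, and extracts the subset belonging to the target
#' SOC (nervous-system events by default).
#'
#' @param reac Tibble of reaction records (`primaryid`, `pt`).
#' @param slice Terminology slice.
#' @param target_soc SOC defining the event set of interest.
#' @return Tibble with one row per `primaryid`: list-columns `pts`
#'   (distinct canonical PTs), `target_pts`, `target_hlgts` (HLGT of each
#'   target PT, same order), counts `n_pts`, `n_target_pts`, `n_unmapped`.
#' @export
event_profiles <- function(reac, slice,
                           target_soc = "Nervous system disorders") {
  stopifnot(inherits(slice, "meddra_slice"))
  d <- reac |>
    mutate(pt_key = canonical_term(.data$pt)) |>
    filter(nzchar(.data$pt_key), !is.na(.data$pt_key)) |>
    distinct(.data$primaryid, .data$pt_key)
  i <- match(d$pt_key, slice$pt_key)
  d$hlgt <- slice$hlgt[i]
  d$soc <- slice$soc[i]
  d |>
    group_by(.data$primaryid) |>
    summarise(
      pts = list(sort(.data$pt_key)),
      target_pts = list(sort(.data$pt_key[!is.na(.data$soc) & .data$soc == target_soc])),
      target_hlgts = list(.data$hlgt[!is.na(.data$soc) & .data$soc == target_soc][
        order(.data$pt_key[!is.na(.data$soc) & .data$soc == target_soc])]),
      n_unmapped = sum(is.na(.data$soc)),
      .groups = "drop"
    ) |>
    mutate(
      n_pts = lengths(.data$pts),
      n_target_pts = lengths(.data$target_pts)
    )
}
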