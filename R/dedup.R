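# FDA-recommended case-version deduplication: within each CASEID keep the
# version with the largest FDA_DT, breaking ties by the largest PRIMARYID;
# deletion lists are applied to the surviving set afterwards.

primaryid_rank <- function(primaryid) {
  # numeric when fully numeric (the practical case), lexicographic fallback
  num <- grepl("^[0-9]+$", primaryid)
  val <- rep(NA_real_, length(primaryid))
  val[num] <- as.numeric(primaryid[num])
  list(numeric = val, text = primaryid)
}

#' Deduplicate case versions
#'
#' For reports sharing a `caseid`, keeps the one with the largest `fda_dt`
#' (receipt date, compared as a zero-padded `YYYYMMDD` integer); ties are
#' broken by the largest `primaryid` (numeric comparison when the id is
#' fully numeric). The result is independent of input row order.
#'
#' @param demo Tibble with at least `primaryid`, `caseid`, `fda_dt`.
#' @return A `dedup_result`: list with `kept` (the surviving DEMO rows),
#'   `kept_primaryids`, `removed_as_duplicate` and `removed_as_deleted`
#'   counts.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("1", "2", "7", "9"),
#'   caseid = c("100", "100", "200", "200"),
#'   fda_dt = c("20230101", "20230301", "20230301", "20230301")
#' )
#' dedup_reports(demo)$kept_primaryids # "2" "9"
#' @export
dedup_reports <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  key <- partial_date_key(demo$fda_dt)
  pr <- primaryid_rank(demo$primaryid)
  ord <- order(demo$caseid, key, pr$numeric, pr$text,
               method = "radix", na.last = FALSE)
  sorted <- demo[ord, , drop = FALSE]
  last_of_case <- !duplicated(sorted$caseid, fromLast = TRUE)
  kept <- sorted[last_of_case, , drop = FALSE]
  kept <- kept[order(primaryid_rank(kept$primaryid)$numeric,
                     kept$primaryid, method = "radix"), , drop = FALSE]
  structure(
    list(kept = as_tibble(kept),
         kept_primaryids = kept$primaryid,
         removed_as_duplicate = nrow(demo) - nrow(kept),
         removed_as_deleted = 0L),
    class = "dedup_result"
  )
}

#' Remove cases named on deletion lists
#'
#' Applied after [dedup_reports()]: any surviving report whose `caseid`
#' appears in the union of the quarters' deletion lists is removed and
#' counted. Unknown caseids on a list have no effect.
#'
#' @param result A `dedup_result`.
#' @param deleted_caseids Character vector (union across quarters).
#' @return The updated `dedup_result`.
#' @export
apply_deletions <- function(result, deleted_caseids) {
  stopifnot(inherits(result, "dedup_result"))
  hit <- result$kept$caseid %in% deleted_caseids
  result$kept <- result$kept[!hit, , drop = FALSE]
  result$kept_primaryids <- result$kept$primaryid
  result$removed_as_deleted <- result$removed_as_deleted + sum(hit)
  result
}

#' @export
print.dedup_result <- function(x, ...) {
  cat("<dedup_result> kept:", nrow(x$kept),
      "| removed as duplicate:", x$removed_as_duplicate,
      "| removed as deleted:", x$removed_as_deleted, "\n")
  invisible(x)
}
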