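# Quarterly FAERS-dialect ASCII ingestion: "$"-delimited tables with one
# header row and no quoting. Header spellings are lower-cased on read so
# legacy and current header variants share one schema.

faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "occp_cod", "reporter_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")
)

outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
role_codes <- c("PS", "SS", "C", "I")

# UTF-8 with per-file Latin-1 fallback; returns the file content as one
# string suitable for read_delim(I(x)).
read_text_lenient <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (!all(validUTF8(txt))) {
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  } else {
    Encoding(txt) <- "UTF-8"
  }
  txt
}

#' Read one FAERS-dialect table
#'
#' Parses a `$`-delimited table with a header row. Rows whose field count
#' does not match the header (e.g. free text containing a literal `$`)
#' are dropped and counted, not fatal; a missing required column is fatal.
#'
#' @param path File path.
#' @param table One of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"indi"`,
#'   `"ther"`.
#' @return A tibble of character columns restricted to the table's schema,
#'   with attributes `rows_in` and `rows_dropped_badfields`.
#' @export
read_faers_table <- function(path, table) {
  table <- match.arg(table, names(faers_schema))
  if (!file.exists(path)) {
    abort(sprintf("FAERS %s table not found: %s", toupper(table), path))
  }
  txt <- read_text_lenient(path)
  df <- suppressWarnings(readr::read_delim(
    I(txt), delim = "$", quote = "", trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, na = c("", "NA")
  ))
  names(df) <- tolower(names(df))
  prob <- readr::problems(df)
  bad_rows <- unique(prob$row) - 1L  # problems() rows count the header
  bad_rows <- bad_rows[bad_rows >= 1L & bad_rows <= nrow(df)]
  rows_in <- nrow(df)
  if (length(bad_rows)) df <- df[-bad_rows, , drop = FALSE]

  need <- faers_schema[[table]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("FAERS %s table %s is missing required column(s): %s",
                  toupper(table), path, paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(df[need])
  attr(out, "rows_in") <- rows_in
  attr(out, "rows_dropped_badfields") <- length(bad_rows)
  out
}

#' Read a deletion list
#'
#' One deleted case identifier per line; blank lines ignored.
#'
#' @param path File path; a missing file yields an empty set.
#' @return Character vector of deleted caseids.
#' @export
read_deleted_list <- function(path) {
  if (is.null(path) || !file.exists(path) || file.size(path) == 0) {
    return(character())
  }
  x <- trimws(readr::read_lines(I(read_text_lenient(path))))
  unique(x[nzchar(x)])
}

coerce_demo <- function(demo) {
  age_num <- suppressWarnings(as.numeric(demo$age))
  n_bad_age <- sum(!is.na(demo$age) & is.na(age_num))
  age_num[!is.na(age_num) & age_num < 0] <- NA_real_
  sex <- toupper(trimws(demo$sex))
  sex[!sex %in% c("F", "M")] <- "UNK"
  age_cod <- toupper(trimws(demo$age_cod))
  age_cod[!age_cod %in% c("DEC", "YR", "MON", "WK", "DY", "HR")] <- NA_character_
  occp <- toupper(trimws(demo$occp_cod))
  occp[!occp %in% c("MD", "PH", "OT", "CN", "LW")] <- NA_character_
  out <- demo
  out$age <- age_num
  out$sex <- sex
  out$age_cod <- age_cod
  out$occp_cod <- occp
  attr(out, "coercion_failures") <- n_bad_age
  out
}

#' Read one quarterly report package
#'
#' Loads the six record tables plus the optional deletion list, validates
#' the schema, and drops (with counts) any non-DEMO row whose `primaryid`
#' does not appear in the quarter's DEMO table.
#'
#' @param dir Directory holding `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `INDI.txt`, `THER.txt` and optionally `DELETED.txt`.
#' @param quarter_label Label such as `"2024Q1"`.
#' @param paths Optional named list overriding individual file locations.
#' @return A `faers_quarter` object: list with one tibble per table,
#'   `deleted_caseids`, `quarter` and a per-table `log` tibble satisfying
#'   `rows_in == rows_kept + rows_dropped`.
#' @export
read_quarter <- function(dir, quarter_label, paths = list()) {
  default_path <- function(tab) file.path(dir, paste0(toupper(tab), ".txt"))
  path_of <- function(tab) paths[[tab]] %||% default_path(tab)

  if (!file.exists(path_of("demo"))) {
    abort(sprintf("Quarter %s: DEMO table is required but %s does not exist.",
                  quarter_label, path_of("demo")))
  }

  tabs <- list()
  log <- list()
  for (tab in names(faers_schema)) {
    p <- path_of(tab)
    if (tab != "demo" && !file.exists(p)) {
      tabs[[tab]] <- as_tibble(stats::setNames(
        rep(list(character()), length(faers_schema[[tab]])),
        faers_schema[[tab]]
      ))
      log[[tab]] <- tibble(table = tab, rows_in = 0L, rows_kept = 0L,
                           rows_dropped = 0L, coercion_failures = 0L)
      next
    }
    x <- read_faers_table(p, tab)
    rows_in <- attr(x, "rows_in")
    dropped_bad <- attr(x, "rows_dropped_badfields")
    coercion <- 0L
    if (tab == "demo") {
      n_before <- nrow(x)
      x <- x |> filter(!is.na(.data$primaryid), !is.na(.data$caseid))
      dropped_bad <- dropped_bad + (n_before - nrow(x))
      x <- coerce_demo(x)
      coercion <- attr(x, "coercion_failures")
    }
    tabs[[tab]] <- x
    log[[tab]] <- tibble(table = tab, rows_in = rows_in,
                         rows_kept = nrow(x),
                         rows_dropped = rows_in - nrow(x),
                         coercion_failures = coercion)
  }

  # orphan rule: non-DEMO rows must reference a DEMO primaryid
  known <- tabs$demo$primaryid
  for (tab in setdiff(names(faers_schema), "demo")) {
    keep <- tabs[[tab]]$primaryid %in% known
    n_orphan <- sum(!keep)
    if (n_orphan > 0L) {
      tabs[[tab]] <- tabs[[tab]][keep, , drop = FALSE]
      log[[tab]]$rows_kept <- nrow(tabs[[tab]])
      log[[tab]]$rows_dropped <- log[[tab]]$rows_dropped + n_orphan
    }
  }

  structure(
    c(tabs, list(
      deleted_caseids = read_deleted_list(path_of("deleted")),
      quarter = quarter_label,
      log = bind_rows(log)
    )),
    class = "faers_quarter"
  )
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("<faers_quarter>", x$quarter, "\n")
  print(x$log)
  cat("deleted caseids:", length(x$deleted_caseids), "\n")
  invisible(x)
}

#' Write a tabular result as CSV
#'
#' UTF-8 CSV with a header row, columns and rows in the order given.
#'
#' @param rows A data frame.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(rows, path, na = "", progress = FALSE)
  invisible(path)
}

# Emit a tibble in the $-delimited dialect (generator output path).
write_faers_table <- function(rows, path) {
  readr::write_delim(rows, path, delim = "$", na = "", quote = "none",
                     progress = FALSE)
  invisible(path)
}
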