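#' Parse FAERS-style partial dates
#'
#' Dates in spontaneous-report tables arrive as `YYYYMMDD`, `YYYYMM` or
#' `YYYY` strings, frequently missing or malformed. The parser is lenient:
#' anything that is not a calendar-valid date at its stated precision
#' becomes missing rather than an error.
#'
#' @param x Character vector of raw date strings.
#' @return A tibble with one row per input and columns `raw`, `year`,
#'   `month`, `day` (integer, `NA` where absent) and `precision`
#'   (`"DAY"`, `"MONTH"`, `"YEAR"` or `NA` for unparseable input).
#' @examples
#' parse_partial_date(c("20230301", "202303", "2023", "20230231", ""))
#' @export
parse_partial_date <- function(x) {
  raw <- trimws(as.character(x))
  n <- length(raw)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  digits <- grepl("^[0-9]+$", raw)
  len <- nchar(raw)

  i4 <- digits & len == 4L
  year[i4] <- as.integer(raw[i4])
  precision[i4] <- "YEAR"

  i6 <- digits & len == 6L
  if (any(i6)) {
    y <- as.integer(substr(raw[i6], 1L, 4L))
    m <- as.integer(substr(raw[i6], 5L, 6L))
    ok <- m >= 1L & m <= 12L
    year[i6][ok] <- y[ok]
    month[i6][ok] <- m[ok]
    precision[i6][ok] <- "MONTH"
  }

  i8 <- digits & len == 8L
  if (any(i8)) {
    d <- as.Date(raw[i8], format = "%Y%m%d")
    ok <- !is.na(d)
    year[i8][ok] <- as.integer(format(d[ok], "%Y"))
    month[i8][ok] <- as.integer(format(d[ok], "%m"))
    day[i8][ok] <- as.integer(format(d[ok], "%d"))
    precision[i8][ok] <- "DAY"
  }

  tibble(raw = raw, year = year, month = month, day = day,
         precision = precision)
}

#' Comparable integer key for a partial date
#'
#' Right-pads `YYYY` with `0101` and `YYYYMM` with `01` so that dates of
#' mixed precision order totally as integers; unparseable input keys as
#' `NA`. Used by the case-version deduplication rule, where receipt dates
#' must be comparable before the report-id tie-break applies.
#'
#' @param x Character vector of raw date strings.
#' @return Integer vector of `YYYYMMDD` keys.
#' @export
partial_date_key <- function(x) {
  pd <- parse_partial_date(x)
  key <- pd$year * 10000L +
    dplyr::coalesce(pd$month, 1L) * 100L +
    dplyr::coalesce(pd$day, 1L)
  key[is.na(pd$precision)] <- NA_integer_
  key
}

#' Full-precision Date from a raw date string
#'
#' Returns a [Date] only when the input carries day precision; `YEAR` and
#' `MONTH` precision inputs yield `NA`, so downstream interval arithmetic
#' (time to onset) never silently imputes within-month positions.
#'
#' @param x Character vector of raw date strings.
#' @return `Date` vector.
#' @export
partial_date_full <- function(x) {
  pd <- parse_partial_date(x)
  out <- rep(as.Date(NA), nrow(pd))
  i <- !is.na(pd$precision) & pd$precision == "DAY"
  out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i],
                            pd$day[i]))
  out
}
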