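#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Round half away from zero
#'
#' Presentation rounding used throughout the package: exact halves round up
#' (2.345 -> 2.35), unlike [round()]'s round-half-even. Applied only when
#' formatting results, never inside estimation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator
#'
#' Computes `100 * numerator / denominator` rounded half-up to two decimals,
#' the convention used for every count-percentage in the cohort tables.
#'
#' @param numerator Count (vectorised).
#' @param denominator Positive count.
#' @return Numeric vector of percentages with two decimals.
#' @examples
#' percent(10870, 20314) # 53.51
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.")
  }
  round_half_up(100 * numerator / denominator, 2)
}

# Canonical form for dictionary/terminology lookups: upper case, trimmed,
# inner whitespace collapsed.
canonical_term <- function(x) {
  stringr::str_squish(toupper(trimws(x)))
}

# Tukey median-of-halves quartiles (exclusive: the median observation is
# left out of both halves when n is odd). Returns c(q1, median, q3).
tukey_quartiles <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(c(q1 = NA_real_, median = NA_real_, q3 = NA_real_))
  med <- stats::median(x)
  if (n %% 2L == 1L) {
    lower <- x[seq_len((n - 1L) / 2L)]
    upper <- x[seq.int((n + 3L) / 2L, length.out = (n - 1L) / 2L)]
  } else {
    lower <- x[seq_len(n / 2L)]
    upper <- x[seq.int(n / 2L + 1L, n)]
  }
  c(q1 = if (length(lower)) stats::median(lower) else med,
    median = med,
    q3 = if (length(upper)) stats::median(upper) else med)
}

# n/missing/mean/sd/median/q1/q3/min/max block for a numeric vector,
# `total` being the cohort size the missing count is measured against.
numeric_block <- function(x, total) {
  ok <- !is.na(x)
  q <- tukey_quartiles(x)
  tibble(
    n = sum(ok),
    missing = total - sum(ok),
    mean = if (any(ok)) mean(x[ok]) else NA_real_,
    sd = if (sum(ok) > 1L) stats::sd(x[ok]) else NA_real_,
    median = q[["median"]],
    q1 = q[["q1"]],
    q3 = q[["q3"]],
    min = if (any(ok)) min(x[ok]) else NA_real_,
    max = if (any(ok)) max(x[ok]) else NA_real_
  )
}
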