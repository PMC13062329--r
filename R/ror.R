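# Reporting odds ratio engine. For a 2x2 of deduplicated report counts
#   a: exposure & event   b: exposure, no event
#   c: event, no exposure d: neither
# ROR = ad/bc, SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d),
# 95% CI = exp(ln ROR +/- z * SE). Signal: a >= 3 and CI lower bound > 1
# (strict). No continuity correction: a zero cell in b, c or d (or a = 0)
# yields an undefined estimate rather than an invented one.

#' Compute reporting odds ratios for 2x2 tables
#'
#' Vectorised over rows of `tbl`. Tables with a zero in any cell are
#' flagged `undefined`: point estimate and interval are `NA` and the
#' signal flag is `FALSE`.
#'
#' @param tbl Tibble/data frame with integer columns `a`, `b`, `c`, `d`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param min_cases Minimum exposed-event count for the signal criterion
#'   (default 3).
#' @return `tbl` with added columns `ror`, `se_log_ror`, `ci_low`,
#'   `ci_high`, `undefined`, `signal`.
#' @examples
#' compute_ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
#' @export
compute_ror <- function(tbl, conf_level = 0.95, min_cases = 3L) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  a <- as.numeric(tbl$a); b <- as.numeric(tbl$b)
  cc <- as.numeric(tbl$c); d <- as.numeric(tbl$d)
  if (any(c(a, b, cc, d) < 0, na.rm = TRUE)) {
    abort("2x2 cells must be nonnegative.")
  }
  undefined <- a == 0 | b == 0 | cc == 0 | d == 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ror <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci_low <- exp(log(ror) - z * se)
  ci_high <- exp(log(ror) + z * se)
  ror[undefined] <- NA_real_
  se[undefined] <- NA_real_
  ci_low[undefined] <- NA_real_
  ci_high[undefined] <- NA_real_
  out <- as_tibble(tbl)
  out$ror <- ror
  out$se_log_ror <- se
  out$ci_low <- ci_low
  out$ci_high <- ci_high
  out$undefined <- undefined
  out$signal <- !undefined & a >= min_cases & ci_low > 1
  out
}

#' Single disproportionality test as a model-like object
#'
#' Broom-compatible wrapper around [compute_ror()] for one 2x2 table.
#'
#' @param a,b,c,d The contingency cells (report counts).
#' @param conf_level,min_cases As in [compute_ror()].
#' @return An object of class `ror_test` with [tidy()] and [glance()]
#'   methods.
#' @examples
#' fit <- ror_test(10, 90, 100, 9900)
#' tidy(fit)
#' @export
ror_test <- function(a, b, c, d, conf_level = 0.95, min_cases = 3L) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L,
            length(d) == 1L)
  res <- compute_ror(tibble(a = a, b = b, c = c, d = d),
                     conf_level = conf_level, min_cases = min_cases)
  structure(list(result = res, conf_level = conf_level,
                 min_cases = min_cases),
            class = "ror_test")
}

#' @export
print.ror_test <- function(x, ...) {
  r <- x$result
  cat("Reporting odds ratio test\n")
  cat(sprintf("  a=%d b=%d c=%d d=%d\n", r$a, r$b, r$c, r$d))
  if (r$undefined) {
    cat("  estimate undefined (zero cell)\n")
  } else {
    cat(sprintf("  ROR %.3f, %g%% CI [%.3f, %.3f], signal: %s\n",
                r$ror, 100 * x$conf_level, r$ci_low, r$ci_high,
                ifelse(r$signal, "yes", "no")))
  }
  invisible(x)
}

#' @rdname ror_test
#' @param x An `ror_test` object.
#' @param ... Unused.
#' @method tidy ror_test
#' @export
tidy.ror_test <- function(x, ...) {
  x$result |>
    transmute(estimate = .data$ror, std.error = .data$se_log_ror,
              conf.low = .data$ci_low, conf.high = .data$ci_high)
}

#' @rdname ror_test
#' @method glance ror_test
#' @export
glance.ror_test <- function(x, ...) {
  x$result |>
    transmute(n = .data$a + .data$b + .data$c + .data$d,
              a = .data$a, ror = .data$ror, ci_low = .data$ci_low,
              ci_high = .data$ci_high, signal = .data$signal,
              undefined = .data$undefined)
}

#' Build one 2x2 table from report id sets
#'
#' Counts each report of the universe exactly once into one cell.
#'
#' @param universe Character vector of report ids (the deduplicated
#'   analysis universe).
#' @param exposed Ids of exposed reports (subset of `universe`).
#' @param with_event Ids of reports carrying the event.
#' @return One-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
build_table <- function(universe, exposed, with_event) {
  exposed <- unique(exposed[exposed %in% universe])
  with_event <- unique(with_event[with_event %in% universe])
  a <- sum(exposed %in% with_event)
  b <- length(exposed) - a
  c <- length(with_event) - a
  d <- length(unique(universe)) - a - b - c
  tibble(a = a, b = b, c = c, d = d)
}

#' Apply the signal criterion
#'
#' `a >= min_cases` and strict `ci_low > 1`; undefined estimates never
#' qualify.
#'
#' @param r Output rows of [compute_ror()].
#' @param min_cases Minimum case count (default 3).
#' @return Logical vector.
#' @export
apply_signal_criterion <- function(r, min_cases = 3L) {
  !r$undefined & r$a >= min_cases & !is.na(r$ci_low) & r$ci_low > 1
}

#' Rank signal rows and keep the strongest
#'
#' Keeps rows flagged as signals, ordered by the CI lower bound
#' (`ci_low`) descending — the conservative signal-strength statistic —
#' with ties broken by `a` descending then event label ascending, and
#' returns the top `k`.
#'
#' @param signals A signal table (rows of [compute_ror()] with an `event`
#'   column).
#' @param k Number of rows to keep.
#' @return The selected rows in rank order.
#' @export
rank_and_select <- function(signals, k) {
  stopifnot(k >= 1)
  signals |>
    filter(.data$signal) |>
    arrange(desc(.data$ci_low), desc(.data$a), .data$event) |>
    slice_head(n = k)
}
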