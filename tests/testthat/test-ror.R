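test_that("point estimate and interval match hand-derived values", {
  r <- compute_ror(tibble::tibble(a = 10, b = 90, c = 100, d = 9900))
  expect_equal(r$ror, 11)  # ad/bc = 99000/9000
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(r$ci_low, o$ci_low, tolerance = 1e-12)
  expect_equal(r$ci_low, 5.56, tolerance = 1e-2)
  expect_true(r$signal)

  sym <- compute_ror(tibble::tibble(a = 5, b = 5, c = 5, d = 5))
  expect_equal(sym$ror, 1)
  expect_false(sym$signal)
})

test_that("zero cells yield undefined results, never corrections", {
  r <- compute_ror(tibble::tibble(a = c(0, 5, 5, 5), b = c(5, 0, 5, 5),
                                  c = c(5, 5, 0, 5), d = c(5, 5, 5, 0)))
  expect_true(all(r$undefined))
  expect_true(all(is.na(r$ror)))
  expect_false(any(r$signal))
  expect_error(compute_ror(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "nonnegative")
})

test_that("the signal criterion is strict on both arms", {
  rows <- tibble::tibble(
    a = c(3, 2, 100, 3),
    ci_low = c(1.01, 50, 1.0, NA),
    undefined = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_equal(apply_signal_criterion(rows), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("estimates agree with the independent oracle on random tables", {
  set.seed(13)
  n <- 2000
  tab <- tibble::tibble(
    a = sample(1:500, n, replace = TRUE),
    b = sample(1:5000, n, replace = TRUE),
    c = sample(1:500, n, replace = TRUE),
    d = sample(1:50000, n, replace = TRUE)
  )
  r <- compute_ror(tab)
  o <- oracle_ror(tab$a, tab$b, tab$c, tab$d)
  expect_lt(max(abs(r$ror / o$ror - 1)), 1e-9)
  expect_lt(max(abs(r$ci_low / o$ci_low - 1)), 1e-9)
  expect_lt(max(abs(r$ci_high / o$ci_high - 1)), 1e-9)

  # exposure-swap symmetry: ROR(c,d,a,b) is the reciprocal
  swapped <- compute_ror(tibble::tibble(a = tab$c, b = tab$d,
                                        c = tab$a, d = tab$b))
  expect_lt(max(abs(r$ror * swapped$ror - 1)), 1e-9)
})

test_that("growing a with other cells fixed strengthens the signal", {
  a <- 1:60
  r <- compute_ror(tibble::tibble(a = a, b = 500, c = 50, d = 5000))
  expect_true(all(diff(r$ror) > 0))
  expect_true(all(diff(r$ci_low) > 0))
})

test_that("build_table counts each report into exactly one cell", {
  universe <- as.character(1:10)
  t1 <- build_table(universe, exposed = c("1", "2", "3"),
                    with_event = c("1", "2", "4"))
  expect_equal(unlist(t1), c(a = 2, b = 1, c = 1, d = 6))
  expect_equal(sum(unlist(t1)), 10)
  # nobody has the event
  t2 <- build_table(universe, c("1", "2"), character())
  expect_equal(unlist(t2)[c("a", "c")], c(a = 0, c = 0))
  # everybody exposed
  t3 <- build_table(universe, universe, c("4", "5"))
  expect_equal(unlist(t3)[c("c", "d")], c(c = 0, d = 0))
})

test_that("ranking orders by CI lower bound with deterministic ties", {
  sig <- tibble::tibble(
    event = c("A", "B", "C", "D", "E"),
    a = c(10, 4, 10, 7, 2),
    ci_low = c(5, 5, 9, 2, 50),
    signal = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  top <- rank_and_select(sig, 2)
  expect_equal(top$event, c("C", "A"))
  all_rows <- rank_and_select(sig, 10)
  expect_equal(all_rows$event, c("C", "A", "B", "D"))  # E is not a signal
})

test_that("ror_test provides broom-style accessors", {
  fit <- ror_test(10, 90, 100, 9900)
  td <- tidy(fit)
  expect_equal(td$estimate, 11)
  gl <- glance(fit)
  expect_true(gl$signal)
  expect_equal(gl$n, 10100)
})
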