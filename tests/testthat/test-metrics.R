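test_that("polarizability counts strict extremes among attitude holders", {
  expect_equal(polarizability(c(0.9, -0.85, 0.1, 0.5), 0.8), 0.5)
  expect_equal(polarizability(rep(0, 10)), 0)
  expect_equal(polarizability(c(1, -1, 1)), 1)
  # the cutoff itself is not extreme (strict inequality)
  expect_equal(polarizability(c(0.8, -0.8)), 0)
  # agents with no attitude are excluded; empty input is 0 by convention
  expect_equal(polarizability(c(NA, 0.9, NA, 0.1)), 0.5)
  expect_equal(polarizability(numeric(0)), 0)
  expect_equal(polarizability(c(NA_real_, NA_real_)), 0)
})

test_that("polarizability is permutation-invariant, monotone in threshold", {
  set.seed(14)
  x <- runif(50, -1, 1)
  expect_equal(polarizability(x, 0.6), polarizability(sample(x), 0.6))
  ths <- seq(0.1, 0.9, by = 0.2)
  vals <- vapply(ths, function(th) polarizability(x, th), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("peak_count takes the max over time", {
  fake <- structure(list(counts = data.frame(t = 0:2, S = c(9, 4, 4),
                                             E = c(0, 5, 3), I = c(1, 1, 1),
                                             R = c(0, 0, 2))),
                    class = "seirja_result")
  expect_equal(peak_count(fake, "E"), 5)
  expect_equal(peak_count(fake, "R"), 2)   # monotone series: final value
  expect_equal(peak_count(fake, "S"), 9)
})

test_that("comment proportions follow the distinct-user convention", {
  mk <- function(sets) structure(list(comm_sets = sets),
                                 class = "seirja_result")
  # all commenters active on day 1 only
  r <- mk(list(1:5, 1:5, integer(0), integer(0)))
  expect_equal(comment_proportion_series(r, steps_per_day = 1)$value,
               c(1, 0, 0))
  # no commenters at all
  expect_equal(comment_proportion_series(mk(list(integer(0), integer(0))),
                                         1)$value, 0)
  # 30 distinct on day 1, 20 new on day 2, none repeating: [0.6, 0.4]
  r2 <- mk(list(integer(0), 1:30, 31:50))
  expect_equal(comment_proportion_series(r2, 1)$value, c(0.6, 0.4))
  # repeat commenters count once per day, so the series may sum past 1
  r3 <- mk(list(integer(0), 1:30, c(1:10, 31:50)))
  expect_equal(comment_proportion_series(r3, 1)$value, c(0.6, 0.6))
  expect_equal(comment_proportion_series(r3, 1, first_day_only = TRUE)$value,
               c(0.6, 0.4))
  # entries are proportions
  expect_true(all(comment_proportion_series(r3, 1)$value <= 1))
})

test_that("rmse matches hand calculations and is a metric-like comparison", {
  a <- curve_series(1:3, c(0.10, 0.20, 0.30))
  b <- curve_series(1:3, c(0.13, 0.16, 0.30))
  expect_equal(curve_rmse(a, a), 0)
  expect_equal(curve_rmse(a, b), sqrt((9 + 16 + 0) / 3))
  expect_equal(curve_rmse(a, b), curve_rmse(b, a))
  # constant 3-point gap over any length is exactly 3
  expect_equal(curve_rmse(rep(0.10, 7), rep(0.13, 7)), 3)
  expect_error(curve_rmse(1:3 / 10, 1:4 / 10), "length")
})

test_that("relative SD follows the percent sample-SD/mean convention", {
  expect_equal(relative_sd(rep(5, 4)), 0)
  expect_equal(relative_sd(c(90, 110)), 14.14214, tolerance = 1e-6)
  expect_equal(relative_sd(42), 0)           # single value, by convention
  expect_equal(relative_sd(c(-1, 1)), 0)     # zero mean, by convention
  expect_error(relative_sd(numeric(0)), "nonempty")
})

test_that("curve series serialize to t,value CSV and back", {
  cs <- curve_series(1:4, c(0.1, 0.25, 0.5, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cs, f)
  expect_identical(readLines(f)[1], "t,value")
  back <- read_curve_csv(f)
  expect_equal(back$t, cs$t)
  expect_equal(back$value, cs$value)
})
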