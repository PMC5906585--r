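# Pattern predicates on constructed time series with known landmarks.

synth_series <- function(values) {
  data.frame(tick = seq_along(values) - 1L, series = values)
}

days_to_ticks <- function(d) round(d * 48)

test_that("peak-in-window detects constructed peaks and rejects end-peaks", {
  n <- 336
  peaked <- synth_series(stats::dnorm(0:n, mean = days_to_ticks(1.5), sd = 20))
  p <- pattern_check("pk", "series", "peak-in-window", c(0, 2))
  r <- check_pattern(peaked, p)
  expect_true(r$pass)
  expect_equal(r$observed, 1.5)
  rising <- synth_series(seq(0, 1, length.out = n + 1))
  expect_false(check_pattern(rising, p)$pass)  # argmax at day 7
  # invariance to uniform rescaling
  scaled <- peaked; scaled$series <- scaled$series * 1e6
  expect_equal(check_pattern(scaled, p), r)
})

test_that("onset-by measures the first sustained rise", {
  n <- 336
  v <- c(rep(100, days_to_ticks(2.5)), seq(100, 400, length.out = n))
  s <- synth_series(v[1:(n + 1)])
  p <- pattern_check("on", "series", "onset-by", c(2, 4))
  r <- check_pattern(s, p)
  expect_true(r$pass)
  expect_gt(r$observed, 2.4)
  # rise before the window start fails
  early <- synth_series(c(rep(100, 10), seq(100, 400, length.out = n - 9)))
  expect_false(check_pattern(early, p)$pass)
  # zero-baseline series: onset relative to the series maximum
  z <- synth_series(c(rep(0, days_to_ticks(3)), seq(0, 50, length.out = 193)))
  expect_true(check_pattern(z, p)$pass)
  # all-zero series has no onset
  expect_false(check_pattern(synth_series(rep(0, n + 1)),
                             pattern_check("z", "series", "onset-by",
                                           c(0, 2)))$pass)
})

test_that("decline-after compares the probe level with the peak", {
  n <- 336
  pulse <- stats::dnorm(0:n, mean = 48, sd = 30)
  p <- pattern_check("dec", "series", "decline-after", c(0, 4),
                     params = list(probe_day = 4, fraction = 0.5))
  expect_true(check_pattern(synth_series(pulse), p)$pass)
  expect_false(check_pattern(synth_series(seq(0, 1, length.out = n + 1)),
                             p)$pass)
})

test_that("sigmoid-shape demands a monotone rise to a plateau", {
  n <- 672  # 14 days
  t <- 0:n
  sig <- 1 / (1 + exp(-(t - 240) / 40))
  p <- pattern_check("sig", "series", "sigmoid-shape", c(0, 14))
  expect_true(check_pattern(synth_series(sig), p)$pass)
  expect_false(check_pattern(synth_series(seq(0, 1, length.out = n + 1)),
                             p)$pass)  # still rising, no plateau
  bumpy <- sig + 0.4 * stats::dnorm(t, 400, 15) * -20
  expect_false(check_pattern(synth_series(pmax(bumpy, 0)), p)$pass)
})

test_that("relative-to-baseline and co-timing behave as documented", {
  n <- 336
  high <- synth_series(5 + stats::dnorm(0:n, 100, 40))
  pb <- pattern_check("rb", "series", "relative-to-baseline", c(1, 5),
                      params = list(baseline = 4, side = "above"))
  expect_true(check_pattern(high, pb)$pass)
  pb2 <- pattern_check("rb2", "series", "relative-to-baseline", c(1, 5),
                       params = list(baseline = 10, side = "above"))
  expect_false(check_pattern(high, pb2)$pass)
  # unset baseline is not evaluable
  pb3 <- pattern_check("rb3", "series", "relative-to-baseline", c(1, 5))
  expect_true(is.na(check_pattern(high, pb3)$pass))
  # co-timing of two peaks
  s <- data.frame(tick = 0:n,
                  a = stats::dnorm(0:n, 96, 20),
                  b = stats::dnorm(0:n, 120, 25))
  pc <- pattern_check("ct", "a", "co-timing", c(0, 7),
                      params = list(other = "b", tol_days = 1))
  r <- check_pattern(s, pc)
  expect_true(r$pass)
  expect_equal(r$observed, 0.5)
  pc2 <- pattern_check("ct2", "a", "co-timing", c(0, 7),
                       params = list(other = "b", tol_days = 0.25))
  expect_false(check_pattern(s, pc2)$pass)
})

test_that("suite reporting covers statuses and respects run length", {
  n <- 336
  s <- data.frame(tick = 0:n,
                  up = seq(0, 1, length.out = n + 1),
                  pk = stats::dnorm(0:n, 72, 30))
  pats <- list(
    pattern_check("good-peak", "pk", "peak-in-window", c(1, 2)),
    pattern_check("bad-peak", "up", "peak-in-window", c(0, 2)),
    pattern_check("known-miss", "up", "peak-in-window", c(0, 2),
                  expected_fail = TRUE),
    pattern_check("too-long", "pk", "peak-in-window", c(0, 14)))
  rep <- run_pattern_suite(s, pats)
  expect_equal(rep$status,
               c("pass", "fail", "expected-fail", "not-evaluated"))
  # empty list -> empty report
  expect_equal(nrow(run_pattern_suite(s, list())), 0)
  # report serialises to JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back), 4)
  expect_equal(back[[1]]$status, "pass")
})

test_that("the shipped pattern suite parses and marks the known miss", {
  pats <- default_patterns()
  expect_gte(length(pats), 8)
  nm <- vapply(pats, function(p) p$name, character(1))
  expect_true("hyaluronan-onset-day-3" %in% nm)
  expect_true(pats[[which(nm == "hyaluronan-onset-day-3")]]$expected_fail)
  expect_false(pats[[which(nm == "macrophage-peak-days-2-4")]]$expected_fail)
})
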