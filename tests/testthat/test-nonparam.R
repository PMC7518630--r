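test_that("IS is 1 for any exact function of clock hour", {
  es <- makeHourPeriodic(days = 2, perHour = 4)
  expect_equal(isValue(interdailyStability(es)), 1)

  # the 2-day toy series with one sample per hour, values 1..24 both days:
  # hourly means equal the values, between-hour variance equals total variance
  toy <- makeHourPeriodic(days = 2, perHour = 1)
  r <- interdailyStability(toy)
  expect_equal(isValue(r), 1)
  expect_equal(r@hourlyMeans, as.numeric(1:24))
  expect_equal(r@overallMean, 12.5)
})

test_that("IS of i.i.d. noise is near zero and within [0, 1] generally", {
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    isValue(interdailyStability(makeSeries(runif(7 * 1440), dt = 60)))
  }, numeric(1))
  expect_true(all(vals < 0.05))
  expect_true(all(vals >= 0))

  # variance decomposition bound on arbitrary fixtures
  for (s in 1:5) {
    set.seed(100 + s)
    v <- isValue(interdailyStability(
      makeSeries(rexp(2 * 1440) * runif(1, 0.1, 2), dt = 60)))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("IS is invariant to affine transforms and errors on bad input", {
  set.seed(3)
  v <- runif(2 * 1440, 0, 0.2)
  base <- isValue(interdailyStability(makeSeries(v, dt = 60)))
  scaled <- isValue(interdailyStability(makeSeries(3.7 * v + 0.4, dt = 60)))
  expect_equal(scaled, base, tolerance = 1e-12)

  expect_error(interdailyStability(makeSeries(runif(180), dt = 60)),
               "empty clock-hour")
  expect_error(interdailyStability(makeSeries(rep(0.1, 2 * 1440), dt = 60)),
               "zero variance")
})

test_that("single-phase IV matches hand and closed-form oracles", {
  # alternating +1/-1: every squared difference 4, population variance 1
  expect_equal(ivSinglePhase(rep(c(1, -1), 10)), 4)

  # linear ramp 1..M: sum diff^2/(M-1) = 1, population variance (M^2-1)/12
  M <- 100
  expect_equal(ivSinglePhase(as.numeric(1:M)), 12 / (M^2 - 1))
  # brute-force direct evaluation of the defining ratio
  y <- as.numeric(1:M)
  expect_equal(ivSinglePhase(y),
               (sum(diff(y)^2) / (M - 1)) / (sum((y - mean(y))^2) / M))

  # i.i.d. normal: E[(Y_k - Y_{k-1})^2] = 2 sigma^2
  set.seed(5)
  expect_equal(ivSinglePhase(rnorm(1e5)), 2, tolerance = 0.05)

  expect_error(ivSinglePhase(c(1)), "at least 2")
  expect_error(ivSinglePhase(rep(2, 10)), "zero variance")
})

test_that("phase-averaged IV reproduces the brute-force worked example", {
  r <- intradailyVariability(as.numeric(1:6), 2L)
  # phases (1,3,5) and (2,4,6): each (4+4)/2 divided by 8/3 = 1.5
  expect_equal(r@perPhase, c(1.5, 1.5))
  expect_equal(ivValue(r), 1.5)
  expect_equal(r@M, 3L)

  # delta = 1 is the direct single-phase IV
  set.seed(8)
  v <- runif(500)
  r1 <- intradailyVariability(v, 1L)
  expect_equal(ivValue(r1), ivSinglePhase(v))
  expect_length(r1@perPhase, 1)
})

test_that("IV phase decomposition conserves the data and handles degeneracy", {
  set.seed(9)
  v <- runif(103)                           # N not a multiple of delta
  d <- 5L
  m <- length(v) %/% d
  phases <- lapply(1:d, function(j) v[(0:(m - 1)) * d + j])
  expect_equal(sort(unlist(phases)), sort(v[1:(d * m)]))

  # zero-variance phase skipped with a warning, average over the rest
  x <- c(1, 5, 1, 3, 1, 4)                  # phase 1 constant
  expect_warning(r <- intradailyVariability(x, 2L), "degenerate phase")
  expect_true(is.na(r@perPhase[1]))
  expect_equal(ivValue(r), r@perPhase[2])
  expect_error(intradailyVariability(rep(1, 10), 2L), "all phases degenerate")
  expect_error(intradailyVariability(runif(10), 6L), ">= 2")
})

test_that("IV is affine invariant and near 2 for subsampled i.i.d. noise", {
  set.seed(10)
  v <- runif(5000)
  expect_equal(ivValue(intradailyVariability(3 * v - 1, 7L)),
               ivValue(intradailyVariability(v, 7L)), tolerance = 1e-12)

  set.seed(11)
  expect_equal(ivValue(intradailyVariability(rnorm(2e5), 60L)), 2,
               tolerance = 0.05)
})

test_that("IV sweep is flat near 2 for white noise, increasing for a slow sinusoid", {
  set.seed(12)
  sw <- ivSweep(rnorm(4e4), deltas = c(1L, 2L, 5L, 10L, 30L, 60L, 120L))
  expect_true(all(sw@ivValues > 1.8 & sw@ivValues < 2.2))

  es <- simulateCircadian(days = 7, dt = 60, harmonicAmplitudes = 0.05,
                          noiseSd = 0, baseline = 0.1)
  sm <- ivSweep(es, deltas = c(1L, 2L, 5L, 10L, 20L, 40L, 60L))
  expect_true(all(diff(sm@ivValues) > 0))

  # single-delta sweep equals the direct computation
  s1 <- ivSweep(es, deltas = 1L)
  expect_equal(s1@ivValues, ivValue(intradailyVariability(es, 1L)))

  # uncomputable deltas surface as NA with a warning
  expect_warning(bad <- ivSweep(runif(10), deltas = c(2L, 8L)), "delta 8")
  expect_true(is.na(bad@ivValues[2]) && !is.na(bad@ivValues[1]))

  tab <- ivSweepTable(sm)
  expect_named(tab, c("delta", "seconds", "iv"))
  expect_equal(tab$seconds, tab$delta * 60)
})

test_that("the recommended subsampling is 5 minutes with a 2-10 minute band", {
  r <- ivRecommendedDelta(5)
  expect_identical(as.integer(r), 60L)
  expect_identical(attr(r, "band"), c(24L, 120L))
  expect_identical(as.integer(ivRecommendedDelta(30)), 10L)
})
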