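test_that("computeEnmo subtracts gravity and truncates at zero", {
  rec <- makeTriax(c(0.6, 0.0, 0.6), c(0.8, 0.0, 0.8), c(0.0, 0.5, 0.5))
  es <- computeEnmo(rec)
  expect_s4_class(es, "EnmoSeries")
  expect_equal(enmoValues(es),
               c(0, 0, sqrt(1.25) - 1))  # unit norm; sub-unit norm; hand calc
  expect_equal(samplingPeriod(es), 5)
  expect_identical(startTime(es), rec$timestamp[1])

  # nonnegative on random signed axis fixtures
  set.seed(7)
  rnd <- makeTriax(rnorm(500), rnorm(500), rnorm(500))
  expect_true(all(enmoValues(computeEnmo(rnd)) >= 0))
})

test_that("computeEnmo rejects gappy grids and empty records", {
  rec <- makeTriax(rep(0.6, 10), 0.8, 0)
  rec$timestamp[7:10] <- rec$timestamp[7:10] + 5   # gap after sample 6
  expect_error(computeEnmo(rec), "after sample 6")
  expect_error(computeEnmo(rec[0, ]), "empty")
})

test_that("cleanRecording keeps gap-free recordings untouched", {
  df <- makeEnmoFrame(days = 3)
  out <- cleanRecording(df)
  expect_length(out$dropped, 0)
  expect_equal(enmoValues(out$series), df$enmo)
  expect_identical(startTime(out$series), df$timestamp[1])

  # shorter than a day, no gaps: unchanged
  sub <- df[1:100, ]
  out2 <- cleanRecording(sub)
  expect_length(out2$dropped, 0)
  expect_equal(length(out2$series), 100L)
})

test_that("cleanRecording drops whole days containing gaps", {
  df <- makeEnmoFrame(days = 3)
  drop_row <- 1440 + 700                   # one missing sample on day 2
  df <- df[-drop_row, ]
  out <- cleanRecording(df)
  expect_equal(out$dropped, "2018-01-02")
  expect_equal(length(out$series), 2L * 1440L)
  # clock alignment preserved: retained samples keep their time of day
  cs <- (as.numeric(format(df$timestamp, "%H")) * 60 +
           as.numeric(format(df$timestamp, "%M")))
  kept <- format(df$timestamp, "%Y-%m-%d") != "2018-01-02"
  expect_equal(enmoValues(out$series), df$enmo[kept])

  # idempotent: cleaning the cleaned series changes nothing
  out2 <- cleanRecording(out$series)
  expect_length(out2$dropped, 0)
  expect_equal(enmoValues(out2$series), enmoValues(out$series))
})

test_that("cleanRecording errors when nothing survives", {
  df <- makeEnmoFrame(days = 1)
  df <- df[-c(100, 800), ]                 # gaps on the only day
  expect_error(cleanRecording(df), "no complete days")
})

test_that("clockPartition splits by clock time and conserves samples", {
  es <- makeSeries(runif(17280, 0, 0.2), dt = 5)   # one full day at 5 s
  parts <- clockPartition(es)
  expect_equal(length(parts$day), 17L * 720L)      # 06:00-23:00
  expect_equal(length(parts$night), 7L * 720L)     # 23:00-06:00
  expect_equal(length(parts$day) + length(parts$night), length(es))

  # within-stream chronological order: day stream = samples 06:00.. in order
  v <- enmoValues(es)
  expect_equal(enmoValues(parts$day), v[(6 * 720 + 1):(23 * 720)])
  expect_equal(enmoValues(parts$night),
               c(v[1:(6 * 720)], v[(23 * 720 + 1):17280]))
})

test_that("clockPartition handles a night-only recording", {
  start <- as.POSIXct("2018-01-01 23:00:00", tz = "UTC")
  es <- makeSeries(runif(7 * 60), dt = 60, start = start)  # 23:00 + 7 h
  expect_warning(parts <- clockPartition(es), "empty day")
  expect_equal(length(parts$day), 0L)
  expect_equal(length(parts$night), 7L * 60L)
})

test_that("dailyProfile averages by clock bin and conserves the mean", {
  # constant series: every bin equals the constant
  esc <- makeSeries(rep(0.1, 2 * 1440), dt = 60)
  prof <- dailyProfile(esc, 60)
  expect_equal(prof$mean, rep(0.1, 24))

  # pure 24-h cosine over 3 whole days: bin means equal the closed-form
  # discrete hourly means of one cycle
  es <- simulateCircadian(days = 3, dt = 60, harmonicAmplitudes = 0.05,
                          noiseSd = 0, baseline = 0.1)
  prof <- dailyProfile(es, 60)
  phase <- -2 * pi * 52200 / 86400
  oracle <- vapply(0:23, function(h)
    mean(0.1 + 0.05 * cos(2 * pi * (h * 3600 + (0:59) * 60) / 86400 + phase)),
    numeric(1))
  expect_equal(prof$mean, oracle, tolerance = 1e-12)
  expect_equal(prof$n, rep(3L * 60L, 24))

  # weighted bin means reconstruct the overall mean
  esr <- makeSeries(runif(5000, 0, 0.3), dt = 60)
  pr <- dailyProfile(esr, 30)
  expect_equal(sum(pr$mean * pr$n, na.rm = TRUE) / sum(pr$n),
               mean(enmoValues(esr)), tolerance = 1e-12)

  expect_error(dailyProfile(esc, 7), "divisor of 1440")
})

test_that("CSV round trip preserves both dialects", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  rec <- makeTriax(rnorm(50), rnorm(50), rnorm(50))
  utils::write.csv(
    data.frame(timestamp = format(rec$timestamp, "%Y-%m-%dT%H:%M:%S"),
               x = rec$x, y = rec$y, z = rec$z),
    tmp, row.names = FALSE)
  back <- readActigraphy(tmp)
  expect_named(back, c("timestamp", "x", "y", "z"))
  expect_equal(back$x, rec$x)

  es <- makeSeries(runif(100, 0, 0.2), dt = 5)
  writeEnmoCsv(es, tmp)
  back2 <- readActigraphy(tmp)
  expect_named(back2, c("timestamp", "enmo"))
  expect_equal(back2$enmo, enmoValues(es))
  expect_identical(back2$timestamp, seriesTimestamps(es))
})
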