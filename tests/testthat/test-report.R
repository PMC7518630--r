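test_that("the metric panel has the contracted columns and flags failures", {
  es <- simulateCircadian(days = 3, dt = 60, seed = 2)
  rows <- computeMetrics(list(a = es), groups = "g1")
  expect_named(rows, c("recording_id", "group", "is", "iv", "iv_delta",
                       "alpha", "alpha_day", "alpha_night", "pov_f", "pov_h",
                       "cosinor_r2"))
  expect_equal(rows$recording_id, "a")
  expect_equal(rows$iv_delta, 5L)          # 5 minutes at dt = 60
  expect_true(all(is.finite(unlist(rows[3:11]))))

  # a recording too short for PoV yields NA (never silent zero) + warning
  short <- simulateCircadian(days = 1, dt = 60, seed = 3)
  w <- capture_warnings(r2 <- computeMetrics(short))
  expect_match(w, "PoV", all = FALSE)
  expect_true(is.na(r2$pov_f) && is.na(r2$pov_h))
  expect_false(any(unlist(r2[3:11]) %in% 0))
})

test_that("group summaries use N-1 sd and are permutation invariant", {
  rows <- data.frame(recording_id = c("a", "b", "c"), group = "g",
                     is = c(1, 2, 3), iv = c(5, 5, 5), iv_delta = 1L,
                     alpha = NA_real_, alpha_day = NA_real_,
                     alpha_night = NA_real_, pov_f = 0.1, pov_h = 0.2,
                     cosinor_r2 = 0.3)
  s <- summarizeGroups(rows, metrics = c("is", "iv"))
  isrow <- s[s$metric == "is", ]
  expect_equal(c(isrow$mean, isrow$sd, isrow$min, isrow$max), c(2, 1, 1, 3))
  expect_equal(summarizeGroups(rows[c(3, 1, 2), ], metrics = c("is", "iv")),
               s)

  single <- summarizeGroups(rows[1, ], metrics = "is")
  expect_equal(single$mean, 1)
  expect_true(is.na(single$sd))
  expect_error(summarizeGroups(rows[0, ]), "empty")
})

test_that("Mann-Whitney comparison is exact for small untied samples", {
  r <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  # enumeration oracle: 2 of the C(6,3) = 20 rank splits are as extreme,
  # doubled for two sides -> 0.1
  expect_equal(r$p, 0.1)
  expect_equal(r$U, 0)
  expect_equal(compareGroups(c(4, 5, 6), c(1, 2, 3))$p, r$p)  # symmetry

  # type-I error calibration at the 5% level
  set.seed(99)
  rej <- mean(replicate(1000, {
    compareGroups(rnorm(10), rnorm(10))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)

  expect_error(compareGroups(numeric(), 1:3), "non-empty")
})

test_that("metric correlations match a brute-force Pearson oracle", {
  rows <- data.frame(is = c(1, 2, 3, 4), iv = c(8, 6, 4, 2),
                     alpha = c(0.2, 0.9, 1.1, 1.4), pov_h = c(1, 2, 3, 4))
  m <- metricCorrelations(rows)
  expect_equal(m["is", "pov_h"], 1)
  expect_equal(m["is", "iv"], -1)
  expect_true(isSymmetric(m))

  # two-pass textbook Pearson
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m["is", "alpha"], pearson(rows$is, rows$alpha),
               tolerance = 1e-12)

  rows$alpha <- 1
  expect_warning(m2 <- metricCorrelations(rows), "constant")
  expect_true(is.na(m2["is", "alpha"]))
  expect_error(metricCorrelations(rows[1:2, ]), "at least 3")
})

test_that("the synthetic cohort reproduces the field's metric relationships", {
  fx <- cohortFixture()
  rows <- fx$rows

  # rhythm-strength metrics track each other; cosinor R^2 tracks PoV(F)
  expect_gt(stats::cor(rows$is, rows$pov_f), 0.9)
  expect_gt(stats::cor(rows$cosinor_r2, rows$pov_f), 0.9)

  # strong-rhythm group separates from the weak group on IS
  p <- compareGroups(rows$is[rows$group == "strong"],
                     rows$is[rows$group == "weak"])$p
  expect_lt(p, 0.05)

  # panel recomputation is deterministic
  again <- suppressWarnings(
    computeMetrics(fx$cohort$series, groups = fx$cohort$truth$group))
  expect_identical(rows, again)
})

test_that("IV correlations are negative at 5 minutes and attenuate at lag one", {
  fx <- cohortFixture()
  d5 <- ivRecommendedDelta(30)
  sw <- ivCorrelationSweep(fx$cohort$series, deltas = d5,
                           baseMetrics = fx$rows)
  expect_equal(nrow(sw), 1)
  expect_true(all(sw[, c("r_iv_is", "r_iv_alpha", "r_iv_povh")] < 0))

  # recordings differing in persistence under heavy white measurement noise:
  # at delta = 1 the white noise masks the differences in consecutive
  # variation, attenuating the IV correlations relative to delta = 10
  set.seed(11)
  n <- 12
  phis <- seq(0.8, 0.99, length.out = n)
  series <- lapply(seq_len(n), function(i) {
    es <- simulateCircadian(days = 4, dt = 30, noiseSd = 0.05,
                            noiseKind = "ar1", phi = phis[i], seed = 100 + i)
    EnmoSeries(pmax(0, enmoValues(es) + rnorm(length(es), 0, 0.05)), dt = 30)
  })
  base <- suppressWarnings(computeMetrics(series))
  sw2 <- ivCorrelationSweep(series, deltas = c(1L, 10L), baseMetrics = base)
  expect_equal(nrow(sw2), 2)
  expect_lt(abs(sw2$r_iv_alpha[1]), abs(sw2$r_iv_alpha[2]))
})

test_that("writeReport bundles summaries, tests and correlations as JSON", {
  fx <- cohortFixture()
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  rep <- writeReport(fx$rows, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_named(back, c("summaries", "tests", "correlations"))
  expect_true(any(back$tests$metric == "is"))
  expect_equal(back$correlations$is[1], 1)
})
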