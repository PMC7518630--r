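# Shared fixture builders; all fixtures are generated in code under fixed
# seeds, nothing is read from disk.

midnight <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")

makeSeries <- function(values, dt = 60, start = midnight) {
  EnmoSeries(values, start = start, dt = dt)
}

# triaxial record on a uniform grid
makeTriax <- function(x, y, z, dt = 5, start = midnight) {
  n <- max(length(x), length(y), length(z))
  data.frame(timestamp = start + (seq_len(n) - 1) * dt,
             x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}

# dialect-B data frame spanning whole days
makeEnmoFrame <- function(days, dt = 60, start = midnight, seed = 1) {
  n <- days * 86400 / dt
  set.seed(seed)
  data.frame(timestamp = start + (seq_len(n) - 1) * dt,
             enmo = runif(n, 0, 0.2))
}

# a series that is an exact function of clock hour (IS = 1 by construction)
makeHourPeriodic <- function(days = 2, perHour = 4, hourValues = 1:24) {
  makeSeries(rep(rep(hourValues, each = perHour), days), dt = 3600 / perHour)
}

# cohort computed once per test session (used by report + acceptance tests)
.cohortCache <- new.env(parent = emptyenv())
cohortFixture <- function() {
  if (is.null(.cohortCache$rows)) {
    co <- simulateCohort(seed = 1)
    rows <- suppressWarnings(
      computeMetrics(co$series, groups = co$truth$group))
    .cohortCache$cohort <- co
    .cohortCache$rows <- rows
  }
  list(cohort = .cohortCache$cohort, rows = .cohortCache$rows)
}
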