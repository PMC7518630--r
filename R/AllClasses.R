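#' @import methods
NULL

setOldClass(c("POSIXct", "POSIXt"))

#' EnmoSeries: a uniformly sampled ENMO activity series
#'
#' Container for a Euclidean-norm-minus-one (ENMO) acceleration series sampled
#' on a fixed grid. ENMO values are in units of g (gravitational acceleration)
#' and are nonnegative by construction (the gravity component is subtracted and
#' negative residuals are floored at zero). The implied timestamp of sample
#' \code{t} (1-based) is \code{start + (t - 1) * dt}.
#'
#' Timestamps are treated as naive local clock time: no daylight-saving
#' adjustment is applied, and readers default to the UTC timezone so that
#' clock arithmetic is pure date arithmetic.
#'
#' @slot start \code{POSIXct} timestamp of the first sample.
#' @slot dt sampling period in seconds (the reference device uses 5 s).
#' @slot values numeric vector of nonnegative ENMO values (g).
#'
#' @seealso [EnmoSeries()] for the user-facing constructor,
#'   [computeEnmo()], [cleanRecording()], [simulateCircadian()].
#' @export
setClass("EnmoSeries",
  representation(start = "POSIXct", dt = "numeric", values = "numeric"))

setValidity("EnmoSeries", function(object) {
  msg <- character()
  if (length(object@start) != 1L || is.na(object@start))
    msg <- c(msg, "'start' must be a single non-missing POSIXct timestamp")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive sampling period in seconds")
  if (anyNA(object@values))
    msg <- c(msg, "'values' must not contain NA")
  else if (length(object@values) && min(object@values) < 0)
    msg <- c(msg, "ENMO 'values' must be nonnegative (truncated at zero)")
  if (length(msg)) msg else TRUE
})

#' Construct an EnmoSeries
#'
#' @param values numeric vector of nonnegative ENMO values (g).
#' @param start POSIXct timestamp of the first sample (or a string parseable
#'   by \code{as.POSIXct} in the \code{tz} timezone).
#' @param dt sampling period in seconds.
#' @param tz timezone used when \code{start} is a string; default "UTC"
#'   (timestamps are treated as naive local time).
#' @return An [EnmoSeries-class] object.
#' @examples
#' es <- EnmoSeries(runif(17280, 0, 0.2), start = "2018-01-01", dt = 5)
#' es
#' @export
EnmoSeries <- function(values, start = "2018-01-01 00:00:00", dt = 5,
                       tz = "UTC") {
  if (!inherits(start, "POSIXct"))
    start <- as.POSIXct(start, tz = tz)
  new("EnmoSeries", start = start, dt = as.numeric(dt),
      values = as.numeric(values))
}

#' Day/night clock partition configuration
#'
#' Defines the two half-open clock intervals used to split a recording into
#' daytime and nighttime streams: day is \code{[dayStart, nightStart)} and
#' night is \code{[nightStart, dayStart)} on the 24-hour clock. Defaults
#' follow the observed rest window of the reference cohort: night from
#' 23:00 to 06:00.
#'
#' @slot dayStart clock time "HH:MM" at which daytime begins.
#' @slot nightStart clock time "HH:MM" at which nighttime begins.
#' @export
setClass("DayNightConfig",
  representation(dayStart = "character", nightStart = "character"))

setValidity("DayNightConfig", function(object) {
  ok <- function(x) length(x) == 1L && grepl("^\\d{1,2}:\\d{2}$", x)
  if (!ok(object@dayStart) || !ok(object@nightStart))
    return("clock times must be single 'HH:MM' strings")
  if (.clockToSeconds(object@dayStart) == .clockToSeconds(object@nightStart))
    return("dayStart and nightStart must differ")
  TRUE
})

#' @rdname DayNightConfig-class
#' @param dayStart,nightStart clock times "HH:MM".
#' @return A \code{DayNightConfig} object.
#' @export
dayNightConfig <- function(dayStart = "06:00", nightStart = "23:00") {
  new("DayNightConfig", dayStart = dayStart, nightStart = nightStart)
}

#' Interdaily stability result
#'
#' @slot isValue the IS statistic: ratio of the mean squared deviation of the
#'   24 clock-hour means from the overall mean to the population variance of
#'   the series. Lies in [0, 1]; 1 means a perfectly repeating daily pattern.
#' @slot hourlyMeans the 24 clock-hour means (g), hour s covering [s-1, s).
#' @slot overallMean overall sample mean (g).
#' @slot nUsed number of samples contributing to each hour bin.
#' @export
setClass("ISResult",
  representation(isValue = "numeric", hourlyMeans = "numeric",
                 overallMean = "numeric", nUsed = "integer"))

#' Intradaily variability result at one subsampling factor
#'
#' @slot delta subsampling factor (samples between retained points).
#' @slot perPhase the per-phase IV values, one per start offset j = 1..delta
#'   (NA for phases skipped as degenerate).
#' @slot ivValue phase-averaged IV (mean of the non-degenerate phases).
#' @slot M length of each subsampled sequence, floor(N / delta).
#' @export
setClass("IVResult",
  representation(delta = "integer", perPhase = "numeric",
                 ivValue = "numeric", M = "integer"))

#' Intradaily variability sweep over subsampling factors
#'
#' @slot deltas strictly increasing subsampling factors.
#' @slot ivValues phase-averaged IV at each factor (NA where not computable).
#' @slot dt sampling period of the underlying series, seconds.
#' @export
setClass("IVSweep",
  representation(deltas = "integer", ivValues = "numeric", dt = "numeric"))

setValidity("IVSweep", function(object) {
  if (length(object@deltas) != length(object@ivValues))
    return("deltas and ivValues must have equal length")
  if (is.unsorted(object@deltas, strictly = TRUE))
    return("deltas must be strictly increasing")
  TRUE
})

#' Detrended fluctuation analysis result
#'
#' @slot scales segment lengths S (samples), strictly increasing.
#' @slot fluctuations overall root-mean-square fluctuation F(S) per scale.
#' @slot alpha DFA scaling exponent: OLS slope of log2 F(S) on log2 S.
#' @slot rSquared coefficient of determination of that log-log regression.
#' @slot profileLength length N of the analysed series.
#' @export
setClass("DFAResult",
  representation(scales = "integer", fluctuations = "numeric",
                 alpha = "numeric", rSquared = "numeric",
                 profileLength = "integer"))

setValidity("DFAResult", function(object) {
  if (length(object@scales) != length(object@fluctuations))
    return("scales and fluctuations must have equal length")
  if (is.unsorted(object@scales, strictly = TRUE))
    return("scales must be strictly increasing")
  TRUE
})

#' One-sided periodogram of an ENMO series
#'
#' Periodogram ordinates \code{I(f) = |sum_t (X_t - mean) exp(-2 pi i f t dt)|^2 / N}
#' on the Fourier grid \code{f_j = j / (N dt)}, \code{j = 0..floor(N/2)}.
#' Two-sided sums are recovered by doubling interior frequencies (the
#' periodogram of a real series is symmetric).
#'
#' @slot freqs Fourier frequencies, Hz.
#' @slot power periodogram ordinates (g^2 per sample); zero at f = 0 because
#'   the mean is removed.
#' @slot dt sampling period, seconds.
#' @slot N series length.
#' @slot nyquist Nyquist frequency 1 / (2 dt), Hz.
#' @export
setClass("Spectrum",
  representation(freqs = "numeric", power = "numeric", dt = "numeric",
                 N = "integer", nyquist = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@freqs) != length(object@power))
    return("freqs and power must have equal length")
  if (length(object@power) && min(object@power) < -1e-12)
    return("power must be nonnegative")
  TRUE
})

#' Proportion-of-variance result
#'
#' Fraction of the series variance captured by narrow periodogram bands
#' around the circadian fundamental frequency (\code{povF}) and around the
#' first \code{nHarmonics} harmonics (\code{povH}).
#'
#' @slot povF fraction captured by the fundamental band.
#' @slot povH fraction captured by the first \code{nHarmonics} bands summed.
#' @slot nHarmonics number of harmonic bands included in \code{povH}.
#' @slot bandPeriodBounds fundamental band limits as periods in hours
#'   (default c(23.5, 24.5)); harmonic k spans frequencies k/upper..k/lower.
#' @slot perHarmonic fraction captured by each harmonic band.
#' @slot variance sample variance of the series (denominator scale, N - 1).
#' @export
setClass("PoVResult",
  representation(povF = "numeric", povH = "numeric", nHarmonics = "integer",
                 bandPeriodBounds = "numeric", perHarmonic = "numeric",
                 variance = "numeric"))

setValidity("PoVResult", function(object) {
  if (length(object@perHarmonic) != object@nHarmonics)
    return("perHarmonic must have one entry per harmonic")
  if (object@povF < -1e-12 || object@povH > 1 + 1e-12 ||
      object@povF > object@povH + 1e-12)
    return("expected 0 <= povF <= povH <= 1")
  TRUE
})
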