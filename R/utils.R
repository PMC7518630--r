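#' @include AllClasses.R AllGenerics.R
NULL

# "HH:MM" -> seconds from midnight
.clockToSeconds <- function(x) {
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2L || anyNA(parts) || parts[1] > 23L || parts[2] > 59L)
    stop("invalid clock time '", x, "' (expected 'HH:MM')", call. = FALSE)
  parts[1] * 3600 + parts[2] * 60
}

# seconds-of-day of a POSIXct under its own timezone (naive clock arithmetic)
.secondsOfDay <- function(ts) {
  lt <- as.POSIXlt(ts)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

# clock seconds-of-day of every implied sample of a series
.clockSeconds <- function(series) {
  n <- length(series@values)
  (.secondsOfDay(series@start) + (seq_len(n) - 1) * series@dt) %% 86400
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @describeIn accessors ENMO values of a series.
setMethod("enmoValues", "EnmoSeries", function(x) x@values)
#' @describeIn accessors start timestamp of a series.
setMethod("startTime", "EnmoSeries", function(x) x@start)
#' @describeIn accessors sampling period (seconds).
setMethod("samplingPeriod", "EnmoSeries", function(x) x@dt)

#' @describeIn EnmoSeries-class number of samples.
#' @param x an EnmoSeries.
#' @export
setMethod("length", "EnmoSeries", function(x) length(x@values))

#' Implied sample timestamps
#'
#' @param x an [EnmoSeries-class] object.
#' @return POSIXct vector \code{start + (t - 1) dt}. After calendar-day gap
#'   cleaning these are implied, not recorded, timestamps: dropped days are
#'   spliced out, but clock times (time of day) remain exact because only
#'   whole days are removed.
#' @export
seriesTimestamps <- function(x) {
  stopifnot(is(x, "EnmoSeries"))
  x@start + (seq_len(length(x)) - 1) * x@dt
}

setMethod("show", "EnmoSeries", function(object) {
  n <- length(object@values)
  cat("EnmoSeries:", n, "samples @", object@dt, "s",
      sprintf("(%.2f days)", n * object@dt / 86400), "\n")
  cat("  start:", format(object@start, "%Y-%m-%d %H:%M:%S"), "\n")
  if (n) cat(sprintf("  ENMO (g): mean %.4f, max %.4f\n",
                     mean(object@values), max(object@values)))
})

setMethod("show", "DayNightConfig", function(object) {
  cat("DayNightConfig: day [", object@dayStart, ", ", object@nightStart,
      "), night [", object@nightStart, ", ", object@dayStart, ")\n", sep = "")
})

setMethod("show", "ISResult", function(object) {
  cat(sprintf("Interdaily stability IS = %.4f\n", object@isValue))
  cat(sprintf("  overall mean %.4f g; hourly means in [%.4f, %.4f]\n",
              object@overallMean, min(object@hourlyMeans),
              max(object@hourlyMeans)))
})

setMethod("show", "IVResult", function(object) {
  cat(sprintf("Intradaily variability IV = %.4f (delta = %d, M = %d)\n",
              object@ivValue, object@delta, object@M))
  nbad <- sum(is.na(object@perPhase))
  if (nbad) cat("  ", nbad, "degenerate phase(s) skipped\n")
})

setMethod("show", "IVSweep", function(object) {
  cat("IV sweep over", length(object@deltas), "subsampling factors",
      sprintf("(%.0f s to %.1f min)\n",
              min(object@deltas) * object@dt,
              max(object@deltas) * object@dt / 60))
  rec <- ivRecommendedDelta(object@dt)
  i <- match(rec, object@deltas)
  if (!is.na(i))
    cat(sprintf("  IV at recommended 5-min subsampling (delta = %d): %.4f\n",
                rec, object@ivValues[i]))
})

setMethod("show", "DFAResult", function(object) {
  cat(sprintf("DFA scaling exponent alpha = %.4f (R^2 = %.4f)\n",
              object@alpha, object@rSquared))
  cat("  scales:", min(object@scales), "to", max(object@scales),
      "samples over", length(object@scales), "scales; N =",
      object@profileLength, "\n")
})

setMethod("show", "Spectrum", function(object) {
  cat("Periodogram:", length(object@freqs), "one-sided frequencies, N =",
      object@N, "\n")
  cat(sprintf("  Nyquist %.4g Hz, resolution %.4g Hz\n",
              object@nyquist, 1 / (object@N * object@dt)))
})

setMethod("show", "PoVResult", function(object) {
  cat(sprintf("Proportion of variance: PoV(F) = %.4f, PoV(H) = %.4f (%d harmonics)\n",
              object@povF, object@povH, object@nHarmonics))
  cat(sprintf("  fundamental band: periods %.1f-%.1f h; per-harmonic: %s\n",
              object@bandPeriodBounds[1], object@bandPeriodBounds[2],
              paste(sprintf("%.4f", object@perHarmonic), collapse = ", ")))
})

#' @describeIn accessors the IS statistic.
setMethod("isValue", "ISResult", function(x) x@isValue)
#' @describeIn accessors the phase-averaged IV statistic.
setMethod("ivValue", "IVResult", function(x) x@ivValue)
#' @describeIn accessors the DFA exponent alpha.
setMethod("scalingExponent", "DFAResult", function(x) x@alpha)
#' @describeIn accessors R^2 of the DFA log-log regression.
setMethod("rSquared", "DFAResult", function(x) x@rSquared)
#' @describeIn accessors Hurst exponent implied by alpha.
setMethod("hurstExponent", "DFAResult", function(x)
  if (x@alpha < 1) x@alpha else x@alpha - 1)
#' @describeIn accessors fundamental-band proportion of variance.
setMethod("povF", "PoVResult", function(x) x@povF)
#' @describeIn accessors harmonic-sum proportion of variance.
setMethod("povH", "PoVResult", function(x) x@povH)
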