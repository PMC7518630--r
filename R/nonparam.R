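#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' @describeIn interdailyStability clock-hour means are pooled across all
#'   available days (partial edge days contribute to whichever hours they
#'   cover); the denominator is the population variance (divide by N). Errors
#'   if any of the 24 clock-hour bins is empty or the series is constant.
setMethod("interdailyStability", "EnmoSeries", function(x, ...) {
  v <- x@values
  n <- length(v)
  if (n < 2L) stop("series too short", call. = FALSE)
  hour <- floor(.clockSeconds(x) / 3600) + 1L  # s = 1..24 covers [s-1, s)
  cnt <- tabulate(hour, nbins = 24L)
  if (any(cnt == 0L))
    stop("empty clock-hour bin(s): ",
         paste(which(cnt == 0L), collapse = ", "), call. = FALSE)
  xbar <- mean(v)
  den <- sum((v - xbar)^2) / n
  if (den == 0) stop("degenerate series: zero variance", call. = FALSE)
  hm <- vapply(split(v, factor(hour, levels = 1:24)), mean, numeric(1))
  num <- sum((hm - xbar)^2) / 24
  new("ISResult", isValue = num / den, hourlyMeans = unname(hm),
      overallMean = xbar, nUsed = cnt)
})

#' IV of a single subsampled sequence
#'
#' The ratio of the mean squared consecutive difference, scaled by 1/(M-1),
#' to the population variance, scaled by 1/M. Exposed mainly for worked
#' examples and testing; [intradailyVariability()] applies it to every phase
#' of a subsampled series and averages.
#'
#' @param y ordered numeric values Y_1..Y_M, M >= 2.
#' @return The IV value (nonnegative scalar).
#' @examples
#' ivSinglePhase(rep(c(1, -1), 10))  # alternating series: exactly 4
#' @export
ivSinglePhase <- function(y) {
  m <- length(y)
  if (m < 2L) stop("need at least 2 values", call. = FALSE)
  den <- sum((y - mean(y))^2) / m
  if (den == 0) stop("degenerate sequence: zero variance", call. = FALSE)
  (sum(diff(y)^2) / (m - 1)) / den
}

#' @describeIn intradailyVariability numeric method. Builds the delta
#'   phase-shifted subsampled sequences (phase j takes samples j, delta + j,
#'   2 delta + j, ..., each of length M = floor(N / delta)), computes IV for
#'   each, and averages. Degenerate (zero-variance) phases are skipped with a
#'   warning and recorded as NA in \code{perPhase}.
setMethod("intradailyVariability", "numeric", function(x, delta = 1L, ...) {
  delta <- as.integer(delta)
  n <- length(x)
  if (delta < 1L || delta > n)
    stop("delta must be in 1..N", call. = FALSE)
  m <- n %/% delta
  if (m < 2L) stop("floor(N / delta) must be >= 2", call. = FALSE)
  Y <- matrix(x[seq_len(delta * m)], nrow = delta)  # Y[j, k] = X[(k-1)delta + j]
  mu <- rowMeans(Y)
  den <- rowSums((Y - mu)^2) / m
  num <- rowSums((Y[, -1L, drop = FALSE] - Y[, -m, drop = FALSE])^2) / (m - 1)
  perPhase <- ifelse(den > 0, num / den, NA_real_)
  if (all(is.na(perPhase)))
    stop("all phases degenerate: zero variance", call. = FALSE)
  if (anyNA(perPhase))
    warning(sum(is.na(perPhase)),
            " degenerate phase(s) skipped in IV average", call. = FALSE)
  new("IVResult", delta = delta, perPhase = as.numeric(perPhase),
      ivValue = mean(perPhase, na.rm = TRUE), M = m)
})

#' @describeIn intradailyVariability method for [EnmoSeries-class].
setMethod("intradailyVariability", "EnmoSeries", function(x, delta = 1L, ...)
  intradailyVariability(x@values, delta = delta))

#' Recommended IV subsampling factor
#'
#' The recommended subsampling interval for IV on high-frequency wrist
#' accelerometry is 5 minutes, with 2 to 10 minutes an acceptable band:
#' shorter intervals are distorted by short-lag autocorrelation, longer ones
#' lose the between-subject contrast in fragmentation.
#'
#' @param dt sampling period of the series, seconds.
#' @return The integer factor corresponding to 5 minutes, with attribute
#'   \code{band} giving the 2- and 10-minute factors.
#' @examples
#' ivRecommendedDelta(5)   # 60
#' @export
ivRecommendedDelta <- function(dt) {
  structure(as.integer(round(300 / dt)),
            band = as.integer(round(c(120, 600) / dt)))
}

.ivSweepCore <- function(v, deltas, dt) {
  deltas <- as.integer(deltas)
  if (is.unsorted(deltas, strictly = TRUE))
    stop("deltas must be strictly increasing", call. = FALSE)
  iv <- vapply(deltas, function(d) {
    tryCatch(intradailyVariability(v, d)@ivValue,
             error = function(e) {
               warning("delta ", d, ": ", conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  new("IVSweep", deltas = deltas, ivValues = iv, dt = dt)
}

#' @describeIn ivSweep method for [EnmoSeries-class]. Default grid 1..720
#'   spans 5 seconds to 60 minutes at the reference 5-second sampling period.
#'   Factors that are not computable (too-short series, degenerate phases)
#'   yield NA with a warning.
setMethod("ivSweep", "EnmoSeries", function(x, deltas = 1:720, ...)
  .ivSweepCore(x@values, deltas, x@dt))

#' @describeIn ivSweep numeric method; \code{dt} gives the sampling period in
#'   seconds (default 5).
#' @param dt sampling period in seconds for the numeric method.
setMethod("ivSweep", "numeric", function(x, deltas = 1:720, dt = 5, ...)
  .ivSweepCore(x, deltas, dt))

#' Tidy an IV sweep
#'
#' @param x an [IVSweep-class].
#' @return data.frame with columns \code{delta}, \code{seconds}, \code{iv}.
#' @export
ivSweepTable <- function(x) {
  stopifnot(is(x, "IVSweep"))
  data.frame(delta = x@deltas, seconds = x@deltas * x@dt, iv = x@ivValues)
}
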