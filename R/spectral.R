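#' @include AllClasses.R AllGenerics.R utils.R
NULL

.periodogramCore <- function(v, dt) {
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  xc <- v - mean(v)
  if (sum(xc^2) == 0) stop("degenerate series: zero variance", call. = FALSE)
  P <- Mod(stats::fft(xc))^2 / n
  half <- n %/% 2L
  j <- 0:half
  new("Spectrum", freqs = j / (n * dt), power = P[j + 1L], dt = dt,
      N = as.integer(n), nyquist = 1 / (2 * dt))
}

#' @describeIn periodogram method for [EnmoSeries-class].
setMethod("periodogram", "EnmoSeries", function(x, ...)
  .periodogramCore(x@values, x@dt))

#' @describeIn periodogram numeric method; \code{dt} is the sampling period
#'   in seconds (default 5).
#' @param dt sampling period in seconds for the numeric method.
setMethod("periodogram", "numeric", function(x, dt = 5, ...)
  .periodogramCore(x, dt))

# two-sided weights on the one-sided grid: interior ordinates count twice
.twoSidedWeights <- function(spec) {
  w <- rep(2, length(spec@freqs))
  w[1] <- 1                               # f = 0
  if (spec@N %% 2L == 0L) w[length(w)] <- 1   # Nyquist bin of an even-N grid
  w
}

#' Fraction of variance in a harmonic frequency band
#'
#' Sums the two-sided periodogram mass over Fourier frequencies f with
#' \code{k / (hi * 3600) <= f <= k / (lo * 3600)} (band edges inclusive),
#' where \code{(lo, hi)} are the fundamental band limits expressed as
#' periods in hours and k is the harmonic order, and divides by the total
#' two-sided mass. By Parseval the result is exactly the fraction of series
#' variance attributable to the band, so a band covering the whole axis
#' returns 1.
#'
#' @param spec a [Spectrum-class] from [periodogram()].
#' @param periodBoundsHours fundamental band limits as periods in hours,
#'   default c(23.5, 24.5) (frequencies 1/88200 to 1/84600 Hz).
#' @param k harmonic order (1 = fundamental), default 1.
#' @return The band's fraction of variance, in [0, 1].
#' @export
bandPower <- function(spec, periodBoundsHours = c(23.5, 24.5), k = 1L) {
  stopifnot(is(spec, "Spectrum"), length(periodBoundsHours) == 2L, k >= 1L)
  lo <- k / (max(periodBoundsHours) * 3600)
  hi <- k / (min(periodBoundsHours) * 3600)
  if (lo > spec@nyquist)
    stop("band beyond the Nyquist frequency", call. = FALSE)
  eps <- 1e-9 / (spec@N * spec@dt)        # tolerance ~ grid spacing * 1e-9
  sel <- spec@freqs >= lo - eps & spec@freqs <= hi + eps
  w <- .twoSidedWeights(spec)
  total <- sum(w * spec@power)
  if (!any(sel)) {
    warning("no Fourier frequency inside the band [",
            signif(lo, 6), ", ", signif(hi, 6), "] Hz", call. = FALSE)
    return(0)
  }
  sum(w[sel] * spec@power[sel]) / total
}

#' @describeIn pov method for [EnmoSeries-class]. The series must span at
#'   least two days, otherwise the fundamental band contains no Fourier
#'   frequency. Band mass is normalised by the total two-sided periodogram
#'   mass (a ratio of sums), which by Parseval equals the population-variance
#'   share and keeps PoV within [0, 1]; the \code{variance} slot records the
#'   N - 1 sample variance, whose scale differs from the Parseval total by a
#'   factor (N - 1)/N.
#' @param bandHours fundamental band limits as periods in hours,
#'   default c(23.5, 24.5).
setMethod("pov", "EnmoSeries", function(x, nHarmonics = 4L,
                                        bandHours = c(23.5, 24.5), ...) {
  nHarmonics <- as.integer(nHarmonics)
  stopifnot(nHarmonics >= 1L)
  n <- length(x)
  if (n * x@dt < 2 * 86400)
    stop("series must span at least 2 days for the fundamental band",
         call. = FALSE)
  spec <- periodogram(x)
  per <- vapply(seq_len(nHarmonics), function(k)
    bandPower(spec, bandHours, k), numeric(1))
  new("PoVResult", povF = per[1], povH = sum(per), nHarmonics = nHarmonics,
      bandPeriodBounds = sort(as.numeric(bandHours)), perHarmonic = per,
      variance = stats::var(x@values))
})

#' @describeIn cosinorR2 fits the linearised two-regressor cosinor
#'   (cosine and sine at the fixed period) by exact least squares and returns
#'   1 - SSE/SST.
setMethod("cosinorR2", "EnmoSeries", function(x, periodHours = 24, ...) {
  v <- x@values
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(v) == 0)
    stop("degenerate series: zero variance", call. = FALSE)
  w <- 2 * pi * (seq_len(n) - 1) * x@dt / (periodHours * 3600)
  fit <- stats::lm.fit(cbind(1, cos(w), sin(w)), v)
  1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
})

#' Tidy a periodogram
#'
#' @param x a [Spectrum-class].
#' @return data.frame with columns \code{freq_hz} and \code{power}.
#' @export
spectrumTable <- function(x) {
  stopifnot(is(x, "Spectrum"))
  data.frame(freq_hz = x@freqs, power = x@power)
}
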