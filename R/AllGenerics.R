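#' @include AllClasses.R
NULL

#' Interdaily stability (IS)
#'
#' Ratio of the between-clock-hour variance of hourly means to the total
#' population variance of the series. IS lies in [0, 1]; 1 indicates a
#' perfectly repeating 24-hour pattern, values near 0 an arrhythmic series.
#'
#' @param x an [EnmoSeries-class] object.
#' @param ... further arguments for methods.
#' @return An [ISResult-class] object.
#' @export
setGeneric("interdailyStability",
           function(x, ...) standardGeneric("interdailyStability"))

#' Phase-averaged intradaily variability (IV)
#'
#' IV of a series subsampled by a factor \code{delta}, averaged over all
#' \code{delta} phase offsets so that every sample is used. IV for one phase
#' is the mean squared consecutive difference (scaled by 1/(M-1)) divided by
#' the population variance (scaled by 1/M); it is about 2 for white noise and
#' lower for smooth, persistent series.
#'
#' @param x an [EnmoSeries-class] object or a numeric vector.
#' @param delta positive integer subsampling factor (samples).
#' @param ... further arguments for methods.
#' @return An [IVResult-class] object.
#' @export
setGeneric("intradailyVariability",
           function(x, delta = 1L, ...) standardGeneric("intradailyVariability"))

#' IV subsampling sweep
#'
#' Computes phase-averaged IV over a grid of subsampling factors (default
#' 1..720, i.e. 5 seconds to 60 minutes at a 5-second sampling period).
#'
#' @param x an [EnmoSeries-class] object or a numeric vector.
#' @param deltas integer vector of subsampling factors, strictly increasing.
#' @param ... further arguments for methods.
#' @return An [IVSweep-class] object.
#' @export
setGeneric("ivSweep",
           function(x, deltas = 1:720, ...) standardGeneric("ivSweep"))

#' DFA scaling exponent
#'
#' Detrended fluctuation analysis: the cumulative mean-centered profile is
#' tiled into non-overlapping segments of length S, a least-squares line is
#' removed per segment, and the scaling exponent alpha is the OLS slope of
#' log2 F(S) on log2 S across the scale grid. alpha = H for stationary
#' (noise-like) series and H + 1 for nonstationary (walk-like) series, where
#' H is the Hurst exponent.
#'
#' @param x an [EnmoSeries-class] object or a numeric vector.
#' @param scales integer scale grid; default [dfaDefaultScales()], the
#'   rounded powers 2^i for i = 4, 4.25, ..., 8 (16 to 256 samples;
#'   1.333 to 21.333 minutes at a 5-second sampling period).
#' @param ... further arguments for methods.
#' @return A [DFAResult-class] object.
#' @export
setGeneric("dfaExponent",
           function(x, scales = dfaDefaultScales(), ...)
             standardGeneric("dfaExponent"))

#' Periodogram
#'
#' One-sided periodogram of the mean-centered series on the Fourier grid,
#' normalised so that the mean of the two-sided ordinates equals the
#' population variance (Parseval).
#'
#' @param x an [EnmoSeries-class] object or a numeric vector.
#' @param ... further arguments for methods (numeric method takes \code{dt}).
#' @return A [Spectrum-class] object.
#' @export
setGeneric("periodogram", function(x, ...) standardGeneric("periodogram"))

#' Proportion of variance at circadian frequencies (PoV)
#'
#' Fraction of series variance captured by narrow periodogram bands around
#' the circadian fundamental frequency (period 23.5 to 24.5 h) and its
#' harmonics.
#'
#' @param x an [EnmoSeries-class] object.
#' @param nHarmonics number of harmonic bands summed into \code{povH}
#'   (default 4).
#' @param ... further arguments for methods.
#' @return A [PoVResult-class] object.
#' @export
setGeneric("pov", function(x, nHarmonics = 4L, ...) standardGeneric("pov"))

#' Cosinor coefficient of determination
#'
#' Least-squares fit of a single cosine with fixed period (default 24 h) plus
#' mean: X_t = M + a cos(2 pi t dt / T) + b sin(2 pi t dt / T). Returns the
#' R^2 of the fit, the parametric comparator to [pov()].
#'
#' @param x an [EnmoSeries-class] object.
#' @param periodHours cosine period in hours, default 24.
#' @param ... further arguments for methods.
#' @return R^2 as a single number in [0, 1].
#' @export
setGeneric("cosinorR2",
           function(x, periodHours = 24, ...) standardGeneric("cosinorR2"))

# ---- accessors -------------------------------------------------------------

#' Accessors for actirhythm result objects
#'
#' Small accessor generics: \code{enmoValues}, \code{startTime} and
#' \code{samplingPeriod} read an [EnmoSeries-class]; \code{isValue},
#' \code{ivValue}, \code{scalingExponent}, \code{rSquared}, \code{povF},
#' \code{povH} extract the headline statistic of the corresponding result
#' object; \code{hurstExponent} maps a DFA exponent to the Hurst exponent
#' (H = alpha for alpha < 1, H = alpha - 1 otherwise).
#'
#' @param x a package object.
#' @name accessors
#' @return The extracted component.
NULL

#' @rdname accessors
#' @export
setGeneric("enmoValues", function(x) standardGeneric("enmoValues"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("samplingPeriod", function(x) standardGeneric("samplingPeriod"))
#' @rdname accessors
#' @export
setGeneric("isValue", function(x) standardGeneric("isValue"))
#' @rdname accessors
#' @export
setGeneric("ivValue", function(x) standardGeneric("ivValue"))
#' @rdname accessors
#' @export
setGeneric("scalingExponent", function(x) standardGeneric("scalingExponent"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("hurstExponent", function(x) standardGeneric("hurstExponent"))
#' @rdname accessors
#' @export
setGeneric("povF", function(x) standardGeneric("povF"))
#' @rdname accessors
#' @export
setGeneric("povH", function(x) standardGeneric("povH"))
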