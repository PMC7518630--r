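#' @include AllClasses.R AllGenerics.R utils.R enmo-io.R
NULL

#' Default DFA scale grid
#'
#' Scales S = round(2^i) for i = 4, 4.25, ..., 8 with duplicates removed:
#' 17 scales from 16 to 256 samples, i.e. 1.333 to 21.333 minutes at a
#' 5-second sampling period. The 16-sample minimum respects the rule of
#' thumb that segments shorter than about 10 samples make the per-segment
#' fluctuation unreliable.
#'
#' @param iRange lower and upper exponent of 2 (default c(4, 8)).
#' @param iStep exponent increment (default 0.25).
#' @return Strictly increasing integer vector of scales.
#' @examples
#' dfaDefaultScales()
#' @export
dfaDefaultScales <- function(iRange = c(4, 8), iStep = 0.25) {
  s <- unique(as.integer(round(2^seq(iRange[1], iRange[2], by = iStep))))
  if (any(s < 4L)) stop("scales below 4 samples are not usable", call. = FALSE)
  s
}

#' DFA profile (mean-centered cumulative sum)
#'
#' @param x numeric series X_1..X_N.
#' @return Z with Z_t = sum_{u<=t} (X_u - mean(X)); Z_N = 0 by telescoping.
#' @examples
#' dfaProfile(c(1, 2, 3))  # -1 -1 0
#' @export
dfaProfile <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  cumsum(x - mean(x))
}

#' Fluctuation at one scale
#'
#' Tiles the profile Z into floor(N/S) non-overlapping segments of length S
#' from the head of the series (trailing remainder discarded), removes an
#' ordinary least-squares line per segment, and returns
#' F(S) = sqrt(mean over segments of the per-segment mean squared residual).
#' The per-segment root-mean-square deviation divides by S (population
#' form), not by degrees of freedom.
#'
#' @param z numeric profile (from [dfaProfile()]).
#' @param s segment length in samples, >= 4.
#' @return F(S), a nonnegative scalar.
#' @export
dfaFluctuation <- function(z, s) {
  s <- as.integer(s)
  if (s < 4L) stop("scale must be >= 4 samples", call. = FALSE)
  k <- length(z) %/% s
  if (k < 1L) stop("series shorter than one segment", call. = FALSE)
  Z <- matrix(z[seq_len(s * k)], nrow = s)
  xc <- seq_len(s) - (s + 1) / 2          # centered within-segment index
  sxx <- sum(xc^2)
  Zc <- Z - rep(colMeans(Z), each = s)
  slope <- colSums(Zc * xc) / sxx
  rss <- colSums(Zc^2) - slope^2 * sxx    # residual SS after line removal
  rss[rss < 0] <- 0                       # guard tiny negative rounding
  sqrt(mean(rss / s))
}

.dfaCore <- function(v, scales) {
  scales <- sort(unique(as.integer(scales)))
  n <- length(v)
  maxUsable <- n %/% 4L
  if (n < 4L * max(scales))
    stop("series too short for scale ", max(scales),
         "; maximum usable scale is ", maxUsable, call. = FALSE)
  if (stats::var(v) == 0)
    stop("constant input: fluctuation is zero at all scales", call. = FALSE)
  z <- dfaProfile(v)
  f <- vapply(scales, function(s) dfaFluctuation(z, s), numeric(1))
  if (any(f <= 0))
    stop("zero fluctuation at scale(s) ",
         paste(scales[f <= 0], collapse = ", "),
         ": log-log fit undefined", call. = FALSE)
  lx <- log2(scales)
  ly <- log2(f)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2])
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 2)
    warning("estimated alpha = ", signif(alpha, 4),
            " outside the expected (0, 2) range", call. = FALSE)
  new("DFAResult", scales = scales, fluctuations = f, alpha = alpha,
      rSquared = r2, profileLength = as.integer(n))
}

#' @describeIn dfaExponent numeric method; requires N >= 4 * max(scales).
setMethod("dfaExponent", "numeric", function(x, scales = dfaDefaultScales(),
                                             ...)
  .dfaCore(x, scales))

#' @describeIn dfaExponent method for [EnmoSeries-class].
setMethod("dfaExponent", "EnmoSeries",
          function(x, scales = dfaDefaultScales(), ...)
  .dfaCore(x@values, scales))

#' Daytime and nighttime DFA exponents
#'
#' Splits the recording by clock time (see [clockPartition()]) and estimates
#' a DFA exponent on each stream. By default each stream is the
#' concatenation of its per-day segments — DFA favours long series, at the
#' price of splice points at the day/night boundaries. With
#' \code{perDay = TRUE} the exponent is instead estimated per calendar day
#' (per night block for the night stream, a night belonging to the date it
#' starts on) and averaged over the blocks long enough for the scale grid.
#'
#' @param x an [EnmoSeries-class] spanning at least one day.
#' @param cfg a [DayNightConfig-class] (default day 06:00, night 23:00).
#' @param scales DFA scale grid (default [dfaDefaultScales()]).
#' @param perDay estimate per day/night block and average instead of
#'   concatenating (default FALSE).
#' @return List with elements \code{day} and \code{night}, each a
#'   [DFAResult-class] (or NULL with a warning if a stream is too short). In
#'   per-day mode \code{alpha} and \code{rSquared} are block averages and
#'   \code{fluctuations} the per-scale geometric mean across blocks.
#' @export
dfaDayNight <- function(x, cfg = dayNightConfig(),
                        scales = dfaDefaultScales(), perDay = FALSE) {
  stopifnot(is(x, "EnmoSeries"))
  isDay <- .clockAssign(x, cfg)
  run <- function(mask, label) {
    v <- x@values[mask]
    if (!perDay) {
      return(tryCatch(.dfaCore(v, scales), error = function(e) {
        warning(label, " stream: ", conditionMessage(e), call. = FALSE)
        NULL
      }))
    }
    key <- .blockDates(x, cfg, isDay)[mask]
    fits <- list()
    for (blk in split(v, key)) {
      r <- tryCatch(.dfaCore(blk, scales), error = function(e) NULL)
      if (!is.null(r)) fits[[length(fits) + 1L]] <- r
    }
    if (!length(fits)) {
      warning(label, " stream: no block long enough for the scale grid",
              call. = FALSE)
      return(NULL)
    }
    fmat <- vapply(fits, function(r) r@fluctuations,
                   numeric(length(fits[[1]]@scales)))
    new("DFAResult", scales = fits[[1]]@scales,
        fluctuations = exp(rowMeans(log(fmat))),
        alpha = mean(vapply(fits, function(r) r@alpha, numeric(1))),
        rSquared = mean(vapply(fits, function(r) r@rSquared, numeric(1))),
        profileLength = as.integer(length(v)))
  }
  list(day = run(isDay, "day"), night = run(!isDay, "night"))
}
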