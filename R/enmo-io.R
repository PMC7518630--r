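#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Read an accelerometry CSV recording
#'
#' Reads either CSV dialect used for wrist accelerometry exports:
#' \itemize{
#'   \item triaxial: header \code{timestamp,x,y,z}, axis values in g;
#'   \item ENMO: header \code{timestamp,enmo}.
#' }
#' Timestamps must be ISO-8601 and strictly increasing. The returned data
#' frame is the raw record; pass it to [cleanRecording()] to obtain a gap-free
#' [EnmoSeries-class].
#'
#' @param path CSV file path.
#' @param tz timezone for parsing timestamps (default "UTC"; timestamps are
#'   treated as naive local time, no daylight-saving handling).
#' @return A data.frame with a POSIXct \code{timestamp} column and either
#'   \code{x,y,z} or \code{enmo} columns.
#' @export
readActigraphy <- function(path, tz = "UTC") {
  df <- as.data.frame(data.table::fread(path, data.table = FALSE,
                                        showProgress = FALSE))
  nm <- tolower(names(df))
  names(df) <- nm
  if (!"timestamp" %in% nm)
    stop("CSV must have a 'timestamp' column", call. = FALSE)
  triax <- all(c("x", "y", "z") %in% nm)
  if (!triax && !"enmo" %in% nm)
    stop("CSV must have columns x,y,z or enmo", call. = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamp at row ",
                      which(is.na(ts))[1], call. = FALSE)
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  out <- if (triax) df[c("timestamp", "x", "y", "z")] else
    df[c("timestamp", "enmo")]
  out$timestamp <- ts
  out
}

#' Write an ENMO series as CSV
#'
#' Writes dialect-B CSV (\code{timestamp,enmo}) with implied timestamps.
#'
#' @param series an [EnmoSeries-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEnmoCsv <- function(series, path) {
  stopifnot(is(series, "EnmoSeries"))
  df <- data.frame(
    timestamp = format(seriesTimestamps(series), "%Y-%m-%dT%H:%M:%S"),
    enmo = series@values)
  data.table::fwrite(df, path)
  invisible(path)
}

# uniform-grid check; returns dt or errors with the offending index
.checkGrid <- function(tsec) {
  if (length(tsec) < 2L) stop("record too short", call. = FALSE)
  gaps <- diff(tsec)
  dt <- stats::median(gaps)
  bad <- which(abs(gaps - dt) >= dt / 100)
  if (length(bad))
    stop("non-uniform sampling grid: gap of ", gaps[bad[1]],
         " s (expected ", dt, " s) after sample ", bad[1], call. = FALSE)
  dt
}

#' Compute ENMO from a triaxial record
#'
#' The Euclidean norm of the three acceleration axes minus 1 g (the gravity
#' component), floored at zero:
#' \code{enmo = max(0, sqrt(x^2 + y^2 + z^2) - 1)}.
#' Requires a gap-free uniform timestamp grid (tolerance dt/100); use
#' [cleanRecording()] for records with dropouts.
#'
#' @param record data.frame with columns \code{timestamp} (POSIXct, strictly
#'   increasing), \code{x}, \code{y}, \code{z} (g). Signed axis values are
#'   accepted; only the norm matters.
#' @return An [EnmoSeries-class].
#' @examples
#' ts <- as.POSIXct("2018-01-01", tz = "UTC") + seq(0, 45, by = 5)
#' rec <- data.frame(timestamp = ts, x = 0.6, y = 0.8, z = 0.5)
#' enmoValues(computeEnmo(rec))[1]  # sqrt(1.25) - 1
#' @export
computeEnmo <- function(record) {
  stopifnot(is.data.frame(record),
            all(c("timestamp", "x", "y", "z") %in% names(record)))
  if (nrow(record) == 0L) stop("empty record", call. = FALSE)
  tsec <- as.numeric(record$timestamp)
  dt <- .checkGrid(tsec)
  enmo <- pmax(0, sqrt(record$x^2 + record$y^2 + record$z^2) - 1)
  new("EnmoSeries", start = record$timestamp[1], dt = dt, values = enmo)
}

# ENMO values of either dialect
.rawEnmo <- function(df) {
  if ("enmo" %in% names(df)) {
    if (any(df$enmo < 0)) stop("negative ENMO values in input", call. = FALSE)
    df$enmo
  } else pmax(0, sqrt(df$x^2 + df$y^2 + df$z^2) - 1)
}

#' Drop calendar days with missing data
#'
#' Scans a (possibly gappy) record for inter-sample gaps larger than
#' 1.5 dt and for interior days with fewer than the expected
#' \code{86400 / dt} samples, drops every affected calendar day in full, and
#' splices the remaining days back together in order. Dropping whole days
#' preserves the clock alignment required by IS, the day/night split and the
#' daily profile: every retained sample keeps its true time of day, although
#' implied dates after a splice are shifted by the number of dropped days.
#' Partial first/last days without internal gaps are retained.
#'
#' @param x a data.frame from [readActigraphy()] (either dialect), or an
#'   [EnmoSeries-class] (returned unchanged with an empty report).
#' @return A list with elements \code{series} (a gap-free
#'   [EnmoSeries-class]) and \code{dropped} (character vector of dropped ISO
#'   dates, possibly empty).
#' @export
cleanRecording <- function(x) {
  if (is(x, "EnmoSeries"))
    return(list(series = x, dropped = character()))
  stopifnot(is.data.frame(x), "timestamp" %in% names(x))
  if (nrow(x) < 2L) stop("record too short", call. = FALSE)
  tsec <- as.numeric(x$timestamp)
  if (is.unsorted(tsec, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  gaps <- diff(tsec)
  dt <- stats::median(gaps)
  dates <- as.Date(format(x$timestamp, "%Y-%m-%d"))
  bad <- character()
  # days touched by a gap
  for (i in which(gaps > 1.5 * dt)) {
    span <- seq(dates[i], dates[i + 1], by = "day")
    bad <- union(bad, format(span))
  }
  # interior days with absent samples
  expected <- round(86400 / dt)
  cnt <- table(format(dates))
  interior <- setdiff(names(cnt), format(range(dates)))
  bad <- union(bad, interior[cnt[interior] < expected])
  keep <- !(format(dates) %in% bad)
  if (!any(keep)) stop("no complete days", call. = FALSE)
  kept <- x[keep, , drop = FALSE]
  # each retained day must itself be on-grid
  ktsec <- as.numeric(kept$timestamp)
  kdates <- format(kept$timestamp, "%Y-%m-%d")
  same <- kdates[-1] == kdates[-length(kdates)]
  jitter <- abs(diff(ktsec) - dt) >= dt / 100 & same
  if (any(jitter))
    stop("non-uniform grid within retained day ", kdates[which(jitter)[1]],
         call. = FALSE)
  series <- new("EnmoSeries", start = kept$timestamp[1], dt = dt,
                values = .rawEnmo(kept))
  list(series = series, dropped = sort(bad))
}

# logical day mask for every sample of a series
.clockAssign <- function(series, cfg) {
  cs <- .clockSeconds(series)
  dayS <- .clockToSeconds(cfg@dayStart)
  nightS <- .clockToSeconds(cfg@nightStart)
  dayLen <- (nightS - dayS) %% 86400
  ((cs - dayS) %% 86400) < dayLen
}

# calendar-date key grouping contiguous day (or night) blocks; night blocks
# spanning midnight are keyed to the date the night starts on
.blockDates <- function(series, cfg, isDay) {
  ts <- seriesTimestamps(series)
  d <- as.Date(format(ts, "%Y-%m-%d"))
  dayS <- .clockToSeconds(cfg@dayStart)
  cs <- .clockSeconds(series)
  key <- d
  key[!isDay & cs < dayS] <- key[!isDay & cs < dayS] - 1
  key
}

#' Split a recording into daytime and nighttime streams
#'
#' Assigns every sample by its clock time to the day interval
#' \code{[dayStart, nightStart)} or the night interval
#' \code{[nightStart, dayStart)} (defaults 06:00 and 23:00), and concatenates
#' the per-day contiguous segments of each class, in chronological order,
#' into one day stream and one night stream. Sample counts are conserved:
#' \code{length(day) + length(night) = length(x)}. The concatenated streams
#' are what the day/night DFA runs on; splice points at the interval
#' boundaries are a documented approximation.
#'
#' @param x an [EnmoSeries-class] spanning at least part of a day.
#' @param cfg a [DayNightConfig-class]; default 06:00 / 23:00.
#' @return A list with [EnmoSeries-class] elements \code{day} and
#'   \code{night} (either may be empty, with a warning).
#' @export
clockPartition <- function(x, cfg = dayNightConfig()) {
  stopifnot(is(x, "EnmoSeries"), is(cfg, "DayNightConfig"))
  isDay <- .clockAssign(x, cfg)
  ts <- seriesTimestamps(x)
  mk <- function(mask, label) {
    if (!any(mask)) {
      warning("empty ", label, " partition", call. = FALSE)
      return(new("EnmoSeries", start = x@start, dt = x@dt,
                 values = numeric()))
    }
    new("EnmoSeries", start = ts[which(mask)[1]], dt = x@dt,
        values = x@values[mask])
  }
  list(day = mk(isDay, "day"), night = mk(!isDay, "night"))
}

#' 24-hour average activity profile
#'
#' Bins every sample by its clock time into \code{1440 / binMinutes} bins and
#' averages within bins, pooling across all recorded days. This is the
#' standard "24-hour time average plot" used to visualise the shape of the
#' daily activity rhythm.
#'
#' @param x an [EnmoSeries-class].
#' @param binMinutes bin width in minutes; must divide 1440 (default 60).
#' @return A data.frame with columns \code{bin} (1-based), \code{start_min}
#'   (bin start, minutes from midnight), \code{mean} (bin mean ENMO, NA for
#'   bins with no samples) and \code{n} (sample count).
#' @export
dailyProfile <- function(x, binMinutes = 60L) {
  stopifnot(is(x, "EnmoSeries"))
  binMinutes <- as.integer(binMinutes)
  if (binMinutes <= 0L || 1440L %% binMinutes != 0L)
    stop("binMinutes must be a positive divisor of 1440", call. = FALSE)
  nb <- 1440L %/% binMinutes
  b <- floor(.clockSeconds(x) / (binMinutes * 60)) + 1L
  n <- tabulate(b, nbins = nb)
  s <- vapply(seq_len(nb), function(i) sum(x@values[b == i]), numeric(1))
  m <- ifelse(n > 0L, s / n, NA_real_)
  if (any(n == 0L))
    warning(sum(n == 0L), " empty profile bin(s)", call. = FALSE)
  data.frame(bin = seq_len(nb), start_min = (seq_len(nb) - 1L) * binMinutes,
             mean = m, n = n)
}
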