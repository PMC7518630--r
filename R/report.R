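#' @include AllClasses.R AllGenerics.R utils.R nonparam.R dfa.R spectral.R
NULL

.metricCols <- c("is", "iv", "iv_delta", "alpha", "alpha_day", "alpha_night",
                 "pov_f", "pov_h", "cosinor_r2")

# run f, returning NA (with a warning naming the recording) on error
.tryMetric <- function(id, what, f) {
  tryCatch(f(), error = function(e) {
    warning(id, " ", what, ": ", conditionMessage(e), call. = FALSE)
    NA_real_
  })
}

#' Compute the full metric panel for a set of recordings
#'
#' For each recording computes IS, phase-averaged IV (at the recommended
#' 5-minute subsampling unless \code{ivDelta} is given), the DFA exponent on
#' the whole series and on the daytime/nighttime streams, PoV at the
#' fundamental and over the first four harmonics, and the cosinor R^2.
#' Metrics that cannot be computed for a recording are reported as NA with a
#' warning, never silently zero.
#'
#' @param series an [EnmoSeries-class] or a (named) list of them.
#' @param ids recording identifiers; defaults to list names or "rec<i>".
#' @param groups optional group label per recording.
#' @param ivDelta IV subsampling factor in samples, or the string "5min"
#'   (default) for [ivRecommendedDelta()] of each recording's dt.
#' @param cfg day/night configuration for the DFA split.
#' @param scales DFA scale grid.
#' @param nHarmonics harmonics summed into pov_h (default 4).
#' @return data.frame with columns \code{recording_id, group, is, iv,
#'   iv_delta, alpha, alpha_day, alpha_night, pov_f, pov_h, cosinor_r2}.
#' @export
computeMetrics <- function(series, ids = NULL, groups = NULL,
                           ivDelta = "5min", cfg = dayNightConfig(),
                           scales = dfaDefaultScales(), nHarmonics = 4L) {
  if (is(series, "EnmoSeries")) series <- list(series)
  stopifnot(is.list(series), all(vapply(series, is, TRUE, "EnmoSeries")))
  nr <- length(series)
  if (is.null(ids))
    ids <- if (!is.null(names(series))) names(series)
           else sprintf("rec%d", seq_len(nr))
  if (is.null(groups)) groups <- rep(NA_character_, nr)
  stopifnot(length(ids) == nr, length(groups) == nr)
  rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    es <- series[[i]]
    d <- if (identical(ivDelta, "5min")) ivRecommendedDelta(es@dt)
         else as.integer(ivDelta)
    dn <- .tryMetric(ids[i], "day/night DFA", function()
      dfaDayNight(es, cfg = cfg, scales = scales))
    p <- .tryMetric(ids[i], "PoV", function() pov(es, nHarmonics))
    rows[[i]] <- data.frame(
      recording_id = ids[i], group = groups[i],
      is = .tryMetric(ids[i], "IS", function()
        interdailyStability(es)@isValue),
      iv = .tryMetric(ids[i], "IV", function()
        intradailyVariability(es, d)@ivValue),
      iv_delta = as.integer(d),
      alpha = .tryMetric(ids[i], "DFA", function()
        dfaExponent(es, scales)@alpha),
      alpha_day = if (is.list(dn) && !is.null(dn$day)) dn$day@alpha
                  else NA_real_,
      alpha_night = if (is.list(dn) && !is.null(dn$night)) dn$night@alpha
                    else NA_real_,
      pov_f = if (is(p, "PoVResult")) p@povF else NA_real_,
      pov_h = if (is(p, "PoVResult")) p@povH else NA_real_,
      cosinor_r2 = .tryMetric(ids[i], "cosinor", function() cosinorR2(es)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-group summary of a metric table
#'
#' Mean, standard deviation (N - 1), minimum and maximum of every metric,
#' within each group. A single-recording group reports NA for the sd.
#'
#' @param rows data.frame from [computeMetrics()].
#' @param metrics metric columns to summarise.
#' @return data.frame with columns group, metric, n, mean, sd, min, max.
#' @export
summarizeGroups <- function(rows, metrics = .metricCols[.metricCols != "iv_delta"]) {
  stopifnot(is.data.frame(rows), "group" %in% names(rows),
            all(metrics %in% names(rows)))
  if (nrow(rows) == 0L) stop("empty metric table", call. = FALSE)
  out <- list()
  for (g in unique(rows$group)) {
    sub <- rows[rows$group %in% g, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]][!is.na(sub[[m]])]
      if (!length(v)) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, n = length(v), mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        min = min(v), max = max(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: the exact null
#' distribution is used for small untied samples, otherwise the normal
#' approximation with continuity and tie corrections (via
#' \code{stats::wilcox.test}). No multiple-testing correction is applied;
#' each comparison is reported at its own level.
#'
#' @param a,b numeric vectors of metric values (NA dropped).
#' @return Named list with \code{U} (the Mann-Whitney U statistic for
#'   \code{a}) and \code{p} (two-sided p-value).
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
compareGroups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pairwise Pearson correlations between metrics
#'
#' @param rows data.frame from [computeMetrics()] with >= 3 complete rows
#'   for the requested metrics.
#' @param metrics metric columns to correlate (default the four headline
#'   statistics IS, IV, alpha, PoV over harmonics).
#' @return Symmetric correlation matrix (pairwise complete observations);
#'   entries involving a constant metric are NA with a warning.
#' @export
metricCorrelations <- function(rows,
                               metrics = c("is", "iv", "alpha", "pov_h")) {
  stopifnot(is.data.frame(rows), all(metrics %in% names(rows)))
  m <- as.matrix(rows[metrics])
  if (sum(stats::complete.cases(m)) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant metric column(s): ",
            paste(metrics[which(sds == 0)], collapse = ", "), call. = FALSE)
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Correlation of IV with the other metrics across the subsampling sweep
#'
#' Recomputes IV for every recording at each subsampling factor and reports
#' the Pearson correlation, across the cohort, of IV with IS, the DFA
#' exponent and PoV over harmonics. Within a suitable subsampling range IV
#' should correlate negatively with all three (fragmentation is the
#' complement of rhythm strength and persistence); at very small factors
#' short-lag autocorrelation and measurement noise attenuate the
#' correlations toward zero.
#'
#' @param series list of [EnmoSeries-class] recordings (>= 3).
#' @param deltas subsampling factors to evaluate.
#' @param baseMetrics optional precomputed [computeMetrics()] table for the
#'   same recordings (saves recomputing IS/alpha/PoV per delta).
#' @return data.frame with columns delta, seconds, r_iv_is, r_iv_alpha,
#'   r_iv_povh.
#' @export
ivCorrelationSweep <- function(series, deltas, baseMetrics = NULL) {
  stopifnot(is.list(series), length(series) >= 3L)
  if (is.null(baseMetrics)) baseMetrics <- computeMetrics(series)
  stopifnot(nrow(baseMetrics) == length(series))
  out <- vector("list", length(deltas))
  dt <- series[[1]]@dt
  for (j in seq_along(deltas)) {
    d <- deltas[j]
    iv <- vapply(series, function(es)
      tryCatch(intradailyVariability(es, d)@ivValue,
               error = function(e) NA_real_), numeric(1))
    out[[j]] <- data.frame(
      delta = as.integer(d), seconds = d * dt,
      r_iv_is = suppressWarnings(
        stats::cor(iv, baseMetrics$is, use = "pairwise.complete.obs")),
      r_iv_alpha = suppressWarnings(
        stats::cor(iv, baseMetrics$alpha, use = "pairwise.complete.obs")),
      r_iv_povh = suppressWarnings(
        stats::cor(iv, baseMetrics$pov_h, use = "pairwise.complete.obs")))
  }
  do.call(rbind, out)
}

#' Write a cohort report
#'
#' Bundles group summaries, pairwise Mann-Whitney comparisons for every
#' metric, and the metric correlation matrix into one JSON report.
#'
#' @param rows data.frame from [computeMetrics()] with a \code{group} column.
#' @param path output JSON path.
#' @return The report list, invisibly.
#' @export
writeReport <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  groups <- unique(rows$group[!is.na(rows$group)])
  tests <- list()
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups))
      for (m in intersect(.metricCols[.metricCols != "iv_delta"], names(rows))) {
        a <- rows[[m]][rows$group %in% groups[i]]
        b <- rows[[m]][rows$group %in% groups[j]]
        if (sum(!is.na(a)) && sum(!is.na(b))) {
          ct <- compareGroups(a, b)
          tests[[length(tests) + 1L]] <- list(
            metric = m, group_a = groups[i], group_b = groups[j],
            U = ct$U, p = ct$p)
        }
      }
  }
  rep <- list(summaries = summarizeGroups(rows),
              tests = tests,
              correlations = as.data.frame(metricCorrelations(rows)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(rep)
}
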