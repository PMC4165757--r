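#' Detect heartbeats by robust threshold crossing
#'
#' Beats are marked at upward crossings of
#' \code{baseline + thresholdFraction * (robust peak - baseline)}, where the
#' baseline is the trace median and the robust peak is the 99th percentile
#' of the samples - high enough to sit on the beat plateau even at slow
#' heart rates where beats occupy a few percent of the samples, while still
#' resistant to amplitude drift and isolated outliers. A refractory
#' lockout suppresses re-triggering, and each beat time is refined to the
#' local maximum of the contiguous supra-threshold run following the
#' crossing. Beat times snap to the sample grid: at 2604 Hz the quantisation
#' (0.38 ms) is far below the period scales of interest.
#'
#' Preprocessing with [preprocess()] first is recommended for noisy traces.
#' A trace with no crossings yields an empty [BeatSeries-class], not an
#' error.
#'
#' @param trace an [ECGTrace-class].
#' @param thresholdFraction fraction of the robust amplitude above baseline,
#'   in (0, 1); default 0.5.
#' @param refractory lockout after each detected beat (s); default 0.1.
#' @return A [BeatSeries-class].
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 10))
#' detectBeats(tr)
#' @export
detectBeats <- function(trace, thresholdFraction = 0.5, refractory = 0.1) {
  stopifnot(is(trace, "ECGTrace"))
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must be in (0, 1)")
  x <- samples(trace)
  fs <- samplingRate(trace)
  baseline <- stats::median(x)
  peak <- stats::quantile(x, 0.99, names = FALSE)
  thr <- baseline + thresholdFraction * (peak - baseline)
  if (peak <= baseline)
    return(BeatSeries(numeric(0), sourceTraceId = traceId(trace)))
  above <- x > thr
  up <- which(!above[-length(above)] & above[-1L]) + 1L
  if (length(above) && above[1L]) up <- c(1L, up)
  refSamp <- max(1L, round(refractory * fs))
  beatIdx <- integer(0)
  lastIdx <- -Inf
  n <- length(x)
  for (i in up) {
    if (i - lastIdx < refSamp) next
    ## local maximum of the contiguous run above threshold
    j <- i
    while (j < n && above[j + 1L]) j <- j + 1L
    pk <- i - 1L + which.max(x[i:j])
    beatIdx <- c(beatIdx, pk)
    lastIdx <- i
  }
  BeatSeries(startTime(trace) + (beatIdx - 1L) / fs,
             sourceTraceId = traceId(trace))
}

traceId <- function(trace) {
  md <- traceMetadata(trace)
  if (!is.null(md$id)) as.character(md$id)
  else paste0(if (!is.null(md$phenotype)) md$phenotype else "trace",
              "/", if (!is.null(md$method)) md$method else "unknown")
}

#' Heartbeat period summaries at fixed offsets into a recording
#'
#' For each offset, takes the first \code{minCycles} inter-beat periods
#' starting at the first beat at or after the offset and reports their mean
#' and standard deviation. The standard protocol averages at least 20 cycles
#' sampled 10 s, 100 s and 1000 s after the start of recording, which
#' removes slow fluctuation over time. A summary is flagged invalid when
#' fewer than \code{minCycles} periods remain after its offset; the achieved
#' count is always reported.
#'
#' @param beats a [BeatSeries-class].
#' @param offsets offsets into the recording (s); default
#'   \code{c(10, 100, 1000)}.
#' @param minCycles cycles per summary; default 20.
#' @return A data.frame with columns \code{offset}, \code{n_cycles},
#'   \code{mean_period}, \code{sd_period}, \code{valid}.
#' @export
periodSummary <- function(beats, offsets = c(10, 100, 1000), minCycles = 20) {
  stopifnot(is(beats, "BeatSeries"))
  bt <- beatTimes(beats)
  pd <- beatPeriods(beats)
  out <- lapply(offsets, function(off) {
    first <- which(bt >= off)[1]
    if (is.na(first) || first > length(pd)) {
      return(data.frame(offset = off, n_cycles = 0L, mean_period = NA_real_,
                        sd_period = NA_real_, valid = FALSE))
    }
    avail <- pd[first:length(pd)]
    n <- as.integer(min(minCycles, length(avail)))
    sel <- avail[seq_len(n)]
    data.frame(offset = off, n_cycles = n, mean_period = mean(sel),
               sd_period = if (n > 1L) stats::sd(sel) else NA_real_,
               valid = n >= minCycles)
  })
  do.call(rbind, out)
}

#' Long-recording stability analysis
#'
#' Quantifies how stable a recording is over minutes, the axis on which
#' noninvasive GaIn recordings outperform invasive needle recordings. The
#' trace is cut into non-overlapping windows; in each, beats are collected
#' and the mean beat peak amplitude (above the trace median baseline) and
#' mean period are computed. The amplitude trend is the least-squares slope
#' of the window amplitude means against time, expressed as a fraction of
#' the first valid window's amplitude per minute; the period coefficient of
#' variation (sd/mean) is taken over all periods. Windows holding fewer
#' than two beats are flagged and excluded from the trend.
#'
#' @param trace an [ECGTrace-class], at least two windows long.
#' @param window window length (s); default 60.
#' @param beats optional pre-computed [BeatSeries-class]; detected with
#'   default [detectBeats()] settings otherwise.
#' @return A [StabilityReport-class].
#' @examples
#' cfg <- phenotypePreset("SERCA-depleted", method = "invasive",
#'                        duration = 300, seed = 2)
#' stabilityAnalysis(generateTrace(cfg))
#' @export
stabilityAnalysis <- function(trace, window = 60, beats = NULL) {
  stopifnot(is(trace, "ECGTrace"))
  dur <- traceDuration(trace)
  if (dur < 2 * window)
    stop("trace must span at least two windows (", 2 * window, " s)")
  if (is.null(beats)) beats <- detectBeats(trace)
  x <- samples(trace)
  fs <- samplingRate(trace)
  baseline <- stats::median(x)
  bt <- beatTimes(beats) - startTime(trace)
  pk <- x[round(bt * fs) + 1L] - baseline
  pd <- beatPeriods(beats)

  nWin <- floor(dur / window)
  centers <- (seq_len(nWin) - 0.5) * window
  ampMeans <- rep(NA_real_, nWin)
  perMeans <- rep(NA_real_, nWin)
  valid <- logical(nWin)
  for (w in seq_len(nWin)) {
    inWin <- which(bt >= (w - 1) * window & bt < w * window)
    if (length(inWin) >= 2L) {
      ampMeans[w] <- mean(pk[inWin])
      perIdx <- inWin[inWin <= length(pd)]
      perMeans[w] <- if (length(perIdx)) mean(pd[perIdx]) else NA_real_
      valid[w] <- TRUE
    }
  }
  trend <- NA_real_
  if (sum(valid) >= 2L) {
    tMin <- centers[valid] / 60
    a <- ampMeans[valid]
    slope <- stats::coef(stats::lm(a ~ tMin))[[2L]]
    trend <- slope / a[1L]           # fraction of initial per minute
  }
  cv <- if (length(pd) > 1L) stats::sd(pd) / mean(pd) else NA_real_
  new("StabilityReport", windowCenters = centers, amplitudeMeans = ampMeans,
      periodMeans = perMeans, windowValid = valid,
      amplitudeTrend = trend, periodCv = cv)
}
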