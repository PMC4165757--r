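#' Extract waveform features from a beat-annotated trace
#'
#' Per beat, three morphology features are measured and averaged across
#' beats:
#' \itemize{
#'   \item \emph{positive duration} - time the waveform spends above
#'     baseline around the beat peak, between the baseline up-crossing and
#'     the next down-crossing. The baseline is the trace median, so
#'     AC-coupling offsets do not bias it.
#'   \item \emph{depolarization slope} - least-squares slope over the
#'     10-90\% amplitude segment of the rising edge (V/s).
#'   \item \emph{repolarization slope} - likewise on the falling edge
#'     (negative, V/s). The 10-90\% convention is robust to smoothing,
#'     unlike a peak derivative.
#' }
#' Beats whose peak does not rise above baseline, or with no baseline
#' crossing inside the trace, are skipped; the number of beats actually
#' used is reported in \code{nBeats}.
#'
#' @param trace an [ECGTrace-class].
#' @param beats a [BeatSeries-class] for this trace with at least one beat.
#' @return A [WaveformFeatures-class].
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 10))
#' extractFeatures(tr, detectBeats(tr))
#' @export
extractFeatures <- function(trace, beats) {
  stopifnot(is(trace, "ECGTrace"), is(beats, "BeatSeries"))
  if (length(beats) < 1L) stop("at least one beat is required")
  x <- samples(trace)
  n <- length(x)
  fs <- samplingRate(trace)
  baseline <- stats::median(x)
  bt <- beatTimes(beats) - startTime(trace)

  durs <- c(); depols <- c(); repols <- c(); peaks <- c()
  for (tb in bt) {
    pkIdx <- round(tb * fs) + 1L
    if (pkIdx < 1L || pkIdx > n) next
    ## allow slight misalignment between marker and the true local max
    lo <- max(1L, pkIdx - 2L); hi <- min(n, pkIdx + 2L)
    pkIdx <- lo - 1L + which.max(x[lo:hi])
    pkVal <- x[pkIdx]
    if (pkVal <= baseline) next
    ## a hair above baseline, so exponentially decaying filter tails that
    ## never quite reach baseline do not inflate the duration
    bl <- baseline + 1e-6 * (pkVal - baseline)
    i <- pkIdx
    while (i > 1L && x[i - 1L] > bl) i <- i - 1L
    j <- pkIdx
    while (j < n && x[j + 1L] > bl) j <- j + 1L
    if (i == 1L && x[1L] > bl) next        # no up-crossing inside trace
    if (j == n && x[n] > bl) next          # no down-crossing inside trace
    sLo <- baseline + 0.1 * (pkVal - baseline)
    sHi <- baseline + 0.9 * (pkVal - baseline)
    riseIdx <- i:pkIdx
    riseIdx <- riseIdx[x[riseIdx] >= sLo & x[riseIdx] <= sHi]
    fallIdx <- pkIdx:j
    fallIdx <- fallIdx[x[fallIdx] >= sLo & x[fallIdx] <= sHi]
    slopeOf <- function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      tt <- idx / fs
      stats::cov(tt, x[idx]) / stats::var(tt)
    }
    depSlope <- slopeOf(riseIdx)
    repSlope <- slopeOf(fallIdx)
    if (!is.finite(depSlope) || !is.finite(repSlope)) next
    durs <- c(durs, (j - i + 1L) / fs)
    depols <- c(depols, depSlope)
    repols <- c(repols, repSlope)
    peaks <- c(peaks, pkVal - baseline)
  }
  used <- length(durs)
  skipped <- length(bt) - used
  if (skipped > 0L)
    message(skipped, " beat(s) skipped (no baseline crossing or flat edge)")
  if (used == 0L)
    stop("no usable beats: none crossed baseline with measurable edges")
  new("WaveformFeatures",
      positiveDuration = mean(durs),
      depolarizationSlope = max(0, mean(depols)),
      repolarizationSlope = min(0, mean(repols)),
      peakAmplitude = mean(peaks), nBeats = as.integer(used))
}

#' Compare invasive and noninvasive waveform features
#'
#' Elementwise noninvasive/invasive feature ratios and the mean-period
#' difference between the two recordings. When the noninvasive recording is
#' a low-pass filtered image of the invasive one, the duration ratio is
#' above 1 and both slope ratios are below 1.
#'
#' @param inv,noninv [WaveformFeatures-class] for the invasive and
#'   noninvasive recording.
#' @param invBeats,noninvBeats matching [BeatSeries-class] objects.
#' @return A [MethodComparison-class].
#' @export
compareMethods <- function(inv, noninv, invBeats, noninvBeats) {
  stopifnot(is(inv, "WaveformFeatures"), is(noninv, "WaveformFeatures"),
            is(invBeats, "BeatSeries"), is(noninvBeats, "BeatSeries"))
  if (nBeats(inv) < 1L || nBeats(noninv) < 1L)
    stop("both feature sets must come from at least one beat")
  if (inv@depolarizationSlope == 0 || inv@repolarizationSlope == 0 ||
      inv@positiveDuration == 0)
    stop("invasive features contain zeros; ratios undefined")
  pd <- function(b) if (length(beatPeriods(b))) mean(beatPeriods(b)) else NA_real_
  new("MethodComparison",
      durationRatio = noninv@positiveDuration / inv@positiveDuration,
      depolSlopeRatio = noninv@depolarizationSlope / inv@depolarizationSlope,
      repolSlopeRatio = abs(noninv@repolarizationSlope) /
        abs(inv@repolarizationSlope),
      periodDifference = pd(noninvBeats) - pd(invBeats))
}

setMethod("show", "MethodComparison", function(object) {
  cat("MethodComparison (noninvasive / invasive)\n")
  cat(sprintf("  positive-duration ratio: %.4f\n", object@durationRatio))
  cat(sprintf("  depol-slope ratio:       %.4f\n", object@depolSlopeRatio))
  cat(sprintf("  repol-slope ratio:       %.4f\n", object@repolSlopeRatio))
  cat(sprintf("  period difference:       %+.4g s\n", object@periodDifference))
  invisible(NULL)
})

#' Fit a first-order interface model between paired traces
#'
#' Least-squares fit of the first-order relative transfer function
#' \deqn{H(s) = \frac{g}{\tau s + 1}}
#' that maps the invasive recording onto the noninvasive one: the fitted
#' \eqn{g} and \eqn{\tau} summarise the DC attenuation and the RC smoothing
#' of the GaIn interface (one rIp // cIp element). The fit minimises the RMS
#' difference between [simulateResponse()] applied to \code{vNeedle} and the
#' observed \code{vGain}, using a deterministic coarse grid over
#' \eqn{(g, \tau)} followed by Nelder-Mead refinement - no random starts, so
#' the result is reproducible. Higher-order interface models are out of
#' scope.
#'
#' @param vNeedle,vGain paired [ECGTrace-class] objects of equal length and
#'   sampling rate.
#' @param tauGrid time-constant starting grid (s); 0 plus a log-spaced grid
#'   from 0.1 ms to 100 ms by default.
#' @return A [FittedInterface-class].
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 5))
#' vg <- simulateResponse(TransferFunction(0.8, c(0.005, 1)), tr)
#' fitRelativeTransfer(tr, vg)
#' @export
fitRelativeTransfer <- function(vNeedle, vGain,
                                tauGrid = c(0, 10^seq(-4, -1, length.out = 13))) {
  stopifnot(is(vNeedle, "ECGTrace"), is(vGain, "ECGTrace"))
  x <- samples(vNeedle)
  y <- samples(vGain)
  if (length(x) != length(y))
    stop("traces must have equal length")
  if (abs(samplingRate(vNeedle) - samplingRate(vGain)) > 1e-9)
    stop("traces must share a sampling rate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input trace; fit is undefined")
  fs <- samplingRate(vNeedle)

  simulate <- function(g, tau) {
    co <- if (tau > 0) ratBilinear(g, c(tau, 1), fs) else list(b = g, a = 1)
    as.numeric(signal::filter(co$b, co$a, x))
  }
  rmsObj <- function(par) {
    g <- par[1L]; tau <- par[2L]
    if (!is.finite(g) || !is.finite(tau) || g <= 0 || tau < 0) return(Inf)
    sqrt(mean((simulate(g, tau) - y)^2))
  }
  ## deterministic coarse grid: gains around the amplitude ratio
  g0 <- stats::sd(y) / stats::sd(x)
  gGrid <- g0 * seq(0.5, 1.5, by = 0.1)
  grid <- expand.grid(g = gGrid, tau = tauGrid)
  vals <- apply(grid, 1L, rmsObj)
  best <- which.min(vals)
  start <- as.numeric(grid[best, ])
  fit <- stats::optim(start, rmsObj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  par <- fit$par
  if (fit$value > vals[best]) par <- start  # refinement must not regress
  new("FittedInterface", dcGain = par[1L],
      timeConstant = max(0, par[2L]),
      residualRms = min(fit$value, vals[best]))
}
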