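#' @import methods
NULL

#' ECGTrace: a uniformly sampled single-channel ECG recording
#'
#' The central container of the package: a voltage time series in volts at a
#' fixed sampling rate, plus free-form metadata (phenotype, recording method,
#' notes). Traces come from [readTrace()], [generateTrace()] or any of the
#' filtering/simulation steps, all of which return a new \code{ECGTrace}.
#'
#' @slot samples numeric vector of voltages (V); finite, length >= 1.
#' @slot samplingRate sampling frequency in Hz (> 0); the pupal recordings
#'   this package targets are digitised at 2604 Hz.
#' @slot startTime time of the first sample in seconds.
#' @slot metadata named list; conventional keys are \code{phenotype}
#'   (\code{"CS"}, \code{"NP"}, \code{"SERCA-depleted"}, \code{"custom"}),
#'   \code{method} (\code{"invasive"}, \code{"noninvasive"},
#'   \code{"simulated"}) and \code{notes}.
#'
#' @seealso [ECGTrace()] constructor, [samples()], [samplingRate()],
#'   [traceTimes()].
#' @export
setClass("ECGTrace",
  representation(samples = "numeric", samplingRate = "numeric",
                 startTime = "numeric", metadata = "list"),
  prototype(samples = numeric(0), samplingRate = 2604,
            startTime = 0, metadata = list()))

setValidity("ECGTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "trace must contain at least one sample")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@startTime) != 1L || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an ECGTrace
#'
#' @param samples numeric vector of voltages in volts.
#' @param samplingRate sampling frequency in Hz.
#' @param startTime time of the first sample (s).
#' @param metadata named list of recording metadata.
#' @return An [ECGTrace-class] object.
#' @examples
#' tr <- ECGTrace(sin(2 * pi * 2 * (0:999) / 1000), samplingRate = 1000)
#' samplingRate(tr)
#' @export
ECGTrace <- function(samples, samplingRate = 2604, startTime = 0,
                     metadata = list()) {
  new("ECGTrace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      startTime = as.numeric(startTime), metadata = metadata)
}

#' BeatShape: piecewise-linear morphology of a single heartbeat
#'
#' One beat is modelled as a trapezoid: a linear rise, a plateau, a linear
#' fall, and an optional triangular undershoot returning to baseline. The
#' shape makes positive duration and both edge slopes analytically known,
#' which is what the feature-extraction tests lean on.
#'
#' @slot amplitude peak amplitude in volts (>= 0).
#' @slot riseTime duration of the rising edge (s).
#' @slot plateauTime duration of the plateau (s).
#' @slot fallTime duration of the falling edge (s).
#' @slot undershootFraction depth of the undershoot as a fraction of
#'   amplitude, in [0, 1).
#' @export
setClass("BeatShape",
  representation(amplitude = "numeric", riseTime = "numeric",
                 plateauTime = "numeric", fallTime = "numeric",
                 undershootFraction = "numeric"),
  prototype(amplitude = 1e-3, riseTime = 0.010, plateauTime = 0.030,
            fallTime = 0.020, undershootFraction = 0))

setValidity("BeatShape", function(object) {
  msg <- character(0)
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  durs <- c(object@riseTime, object@plateauTime, object@fallTime)
  if (any(durs < 0)) msg <- c(msg, "all durations must be >= 0")
  if (sum(durs) <= 0) msg <- c(msg, "total beat duration must be > 0")
  if (object@undershootFraction < 0 || object@undershootFraction >= 1)
    msg <- c(msg, "undershootFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname BeatShape-class
#' @param amplitude,riseTime,plateauTime,fallTime,undershootFraction see slots.
#' @return A [BeatShape-class] object.
#' @export
BeatShape <- function(amplitude = 1e-3, riseTime = 0.010, plateauTime = 0.030,
                      fallTime = 0.020, undershootFraction = 0) {
  new("BeatShape", amplitude = amplitude, riseTime = riseTime,
      plateauTime = plateauTime, fallTime = fallTime,
      undershootFraction = undershootFraction)
}

#' SyntheticConfig: full description of a synthetic pupal ECG recording
#'
#' Bundles the physiology (heart rate, beat shape), the contamination
#' (powerline, white noise, baseline wander), the per-beat period jitter,
#' and the slow drifts that distinguish invasive from noninvasive
#' recordings. See [syntheticConfig()] and [phenotypePreset()].
#'
#' @slot heartRate mean heart rate in Hz (> 0).
#' @slot duration recording length in seconds (> 0).
#' @slot samplingRate sampling frequency in Hz; default 2604.
#' @slot beatShape a [BeatShape-class].
#' @slot powerlineAmplitude amplitude of mains interference (V).
#' @slot powerlineFreq mains frequency (Hz); default 60.
#' @slot whiteNoiseSd white measurement noise standard deviation (V).
#' @slot baselineWanderAmplitude amplitude of slow baseline oscillation (V).
#' @slot baselineWanderFreq baseline wander frequency (Hz).
#' @slot periodJitterSd per-beat normal period jitter sd (s), truncated so
#'   periods stay positive.
#' @slot amplitudeDriftRate fractional amplitude loss per minute
#'   (beat amplitude follows (1 - r)^(t/60)).
#' @slot periodDriftRate fractional period lengthening per minute (additive:
#'   period grows linearly in time).
#' @slot amplifierEnabled apply the AC-coupled amplifier front-end stage.
#' @slot amplifierGainDb amplifier gain in dB (hardware maximum 80 dB).
#' @slot amplifierLowCut,amplifierHighCut passband corners in Hz (5 Hz and
#'   10 kHz on the bench amplifier).
#' @slot seed integer RNG seed; identical configs give bitwise-identical
#'   traces.
#' @slot phenotypeLabel one of "CS", "NP", "SERCA-depleted", "custom".
#' @export
setClass("SyntheticConfig",
  representation(heartRate = "numeric", duration = "numeric",
                 samplingRate = "numeric", beatShape = "BeatShape",
                 powerlineAmplitude = "numeric", powerlineFreq = "numeric",
                 whiteNoiseSd = "numeric", baselineWanderAmplitude = "numeric",
                 baselineWanderFreq = "numeric", periodJitterSd = "numeric",
                 amplitudeDriftRate = "numeric", periodDriftRate = "numeric",
                 amplifierEnabled = "logical", amplifierGainDb = "numeric",
                 amplifierLowCut = "numeric", amplifierHighCut = "numeric",
                 seed = "numeric", phenotypeLabel = "character"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  if (object@heartRate <= 0) msg <- c(msg, "heartRate must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@samplingRate <= 2 * object@powerlineFreq)
    msg <- c(msg, "samplingRate must exceed twice the powerline frequency")
  if (object@periodJitterSd < 0) msg <- c(msg, "periodJitterSd must be >= 0")
  if (object@whiteNoiseSd < 0) msg <- c(msg, "whiteNoiseSd must be >= 0")
  tMin <- object@duration / 60
  if (object@amplitudeDriftRate * tMin >= 1)
    msg <- c(msg, "amplitude drift would drive amplitude non-positive over the recording")
  if (1 + object@periodDriftRate * tMin <= 0)
    msg <- c(msg, "period drift would drive the period non-positive over the recording")
  if (!object@phenotypeLabel %in% c("CS", "NP", "SERCA-depleted", "custom"))
    msg <- c(msg, "phenotypeLabel must be one of CS, NP, SERCA-depleted, custom")
  if (length(msg)) msg else TRUE
})

#' BeatSeries: detected beat times and inter-beat periods
#'
#' @slot beatTimes strictly increasing beat event times (s).
#' @slot periods successive differences of beatTimes (s); always one shorter.
#' @slot sourceTraceId identifier of the trace the beats came from.
#' @export
setClass("BeatSeries",
  representation(beatTimes = "numeric", periods = "numeric",
                 sourceTraceId = "character"),
  prototype(beatTimes = numeric(0), periods = numeric(0), sourceTraceId = ""))

setValidity("BeatSeries", function(object) {
  msg <- character(0)
  n <- length(object@beatTimes)
  if (n > 1L && any(diff(object@beatTimes) <= 0))
    msg <- c(msg, "beatTimes must be strictly increasing")
  if (length(object@periods) != max(0L, n - 1L))
    msg <- c(msg, "periods must have length length(beatTimes) - 1")
  if (length(object@periods) && any(object@periods <= 0))
    msg <- c(msg, "all periods must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BeatSeries-class
#' @param beatTimes strictly increasing beat times in seconds.
#' @param sourceTraceId identifier string.
#' @return A [BeatSeries-class]; periods are computed as successive
#'   differences.
#' @export
BeatSeries <- function(beatTimes, sourceTraceId = "") {
  beatTimes <- as.numeric(beatTimes)
  new("BeatSeries", beatTimes = beatTimes,
      periods = if (length(beatTimes) > 1L) diff(beatTimes) else numeric(0),
      sourceTraceId = sourceTraceId)
}

#' TransferFunction: a rational function of the Laplace variable s
#'
#' Numerator and denominator coefficients are stored in descending powers of
#' s, denominator normalised to a leading coefficient of 1. Only proper
#' functions (numerator degree <= denominator degree) are representable, so
#' every object can be discretised and simulated.
#'
#' @slot numerator numeric coefficients, descending powers of s.
#' @slot denominator numeric coefficients, descending powers of s; leading
#'   coefficient nonzero.
#' @seealso [TransferFunction()], [bode()], [simulateResponse()],
#'   [relativeTransfer()].
#' @export
setClass("TransferFunction",
  representation(numerator = "numeric", denominator = "numeric"),
  prototype(numerator = 1, denominator = 1))

setValidity("TransferFunction", function(object) {
  msg <- character(0)
  den <- object@denominator
  if (length(den) == 0L || den[1L] == 0)
    msg <- c(msg, "leading denominator coefficient must be nonzero")
  if (length(polyTrim(object@numerator)) > length(den))
    msg <- c(msg, "numerator degree must not exceed denominator degree")
  if (!all(is.finite(object@numerator)) || !all(is.finite(den)))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname TransferFunction-class
#' @param numerator,denominator coefficient vectors in descending powers of s.
#' @return A [TransferFunction-class] with the denominator normalised to
#'   leading coefficient 1.
#' @examples
#' lp <- TransferFunction(1, c(0.005, 1))  # first-order low-pass, tau = 5 ms
#' bode(lp, c(1, 10, 100))
#' @export
TransferFunction <- function(numerator, denominator) {
  r <- ratNew(numerator, denominator)
  new("TransferFunction", numerator = r$num, denominator = r$den)
}

#' Equivalent-circuit models of the three electrode interfaces
#'
#' Lumped RC descriptions of the electrode-tissue interface for the three
#' recording methods. Each model is a series chain from the cardiac source
#' through interface and bulk impedances into the amplifier load
#' (rLoad // cLoad), from which [needleTransfer()], [gelledTransfer()] and
#' [gainTransfer()] derive voltage-divider transfer functions.
#'
#' \describe{
#'   \item{NeedleElectrodeModel}{Invasive tungsten needle: the needle-hemocoel
#'     interface is cEh // rEh, in series with the hemocoel bulk resistance
#'     rBody.}
#'   \item{GelledElectrodeModel}{Surface electrode with electrolyte gel:
#'     electrolyte resistance rE, electrode-electrolyte interface cEe // rEe,
#'     puparium resistance rP, puparium-hemocoel interface cPh // rPh, plus a
#'     DC interface potential ePe across the ion-semipermeable puparium
#'     (a Nernst potential, see [nernstPotential()]) that enters as an
#'     additive series offset, not as part of the transfer function.}
#'   \item{GaInElectrodeModel}{Liquid-metal (GaIn) dry-contact electrode:
#'     interface impedance rIp // cIp plus a series DC resistance rSeries.}
#' }
#'
#' @slot cEh,rEh,rBody needle model components (F, ohm, ohm).
#' @slot rE,rP,cEe,rEe,cPh,rPh,ePe gelled model components.
#' @slot rIp,cIp,rSeries GaIn model components.
#' @slot rLoad,cLoad amplifier input load for all models (ohm, F).
#' @name ElectrodeModels
#' @aliases NeedleElectrodeModel-class GelledElectrodeModel-class
#'   GaInElectrodeModel-class
NULL

#' @export
setClass("NeedleElectrodeModel",
  representation(cEh = "numeric", rEh = "numeric", rBody = "numeric",
                 rLoad = "numeric", cLoad = "numeric"))

#' @export
setClass("GelledElectrodeModel",
  representation(rE = "numeric", rP = "numeric", cEe = "numeric",
                 rEe = "numeric", cPh = "numeric", rPh = "numeric",
                 ePe = "numeric", rLoad = "numeric", cLoad = "numeric"))

#' @export
setClass("GaInElectrodeModel",
  representation(rIp = "numeric", cIp = "numeric", rSeries = "numeric",
                 rLoad = "numeric", cLoad = "numeric"))

.checkRC <- function(res, caps) {
  msg <- character(0)
  if (any(res <= 0)) msg <- c(msg, "all resistances must be > 0")
  if (any(caps < 0)) msg <- c(msg, "capacitances must be >= 0")
  if (!all(is.finite(c(res, caps)))) msg <- c(msg, "components must be finite")
  msg
}

setValidity("NeedleElectrodeModel", function(object) {
  msg <- .checkRC(c(object@rEh, object@rBody, object@rLoad),
                  c(object@cEh, object@cLoad))
  if (length(msg)) msg else TRUE
})

setValidity("GelledElectrodeModel", function(object) {
  msg <- .checkRC(c(object@rE, object@rP, object@rEe, object@rPh, object@rLoad),
                  c(object@cEe, object@cPh, object@cLoad))
  if (length(msg)) msg else TRUE
})

setValidity("GaInElectrodeModel", function(object) {
  msg <- .checkRC(c(object@rIp, object@rSeries, object@rLoad),
                  c(object@cIp, object@cLoad))
  if (length(msg)) msg else TRUE
})

#' WaveformFeatures: per-recording average beat morphology
#'
#' @slot positiveDuration mean time per beat above baseline (s).
#' @slot depolarizationSlope mean rising-edge slope (V/s, >= 0).
#' @slot repolarizationSlope mean falling-edge slope (V/s, <= 0).
#' @slot peakAmplitude mean beat peak above baseline (V).
#' @slot nBeats number of beats the means are taken over.
#' @export
setClass("WaveformFeatures",
  representation(positiveDuration = "numeric",
                 depolarizationSlope = "numeric",
                 repolarizationSlope = "numeric",
                 peakAmplitude = "numeric", nBeats = "integer"))

setValidity("WaveformFeatures", function(object) {
  msg <- character(0)
  if (object@nBeats > 0L && object@positiveDuration <= 0)
    msg <- c(msg, "positiveDuration must be > 0 when beats are present")
  if (object@nBeats > 0L && object@depolarizationSlope < 0)
    msg <- c(msg, "depolarizationSlope must be >= 0")
  if (object@nBeats > 0L && object@repolarizationSlope > 0)
    msg <- c(msg, "repolarizationSlope must be <= 0")
  if (length(msg)) msg else TRUE
})

#' StabilityReport: windowed amplitude/period trends over a long recording
#'
#' @slot windowCenters centres of the non-overlapping analysis windows (s).
#' @slot amplitudeMeans mean beat peak amplitude per window (V); NA where a
#'   window held fewer than two beats.
#' @slot periodMeans mean beat period per window (s); NA as above.
#' @slot windowValid which windows entered the trend fit.
#' @slot amplitudeTrend least-squares slope of the window amplitude means,
#'   expressed as a fraction of the initial amplitude per minute.
#' @slot periodCv coefficient of variation (sd/mean) of all periods.
#' @export
setClass("StabilityReport",
  representation(windowCenters = "numeric", amplitudeMeans = "numeric",
                 periodMeans = "numeric", windowValid = "logical",
                 amplitudeTrend = "numeric", periodCv = "numeric"))

setValidity("StabilityReport", function(object) {
  n <- length(object@windowCenters)
  msg <- character(0)
  if (length(object@amplitudeMeans) != n || length(object@periodMeans) != n ||
      length(object@windowValid) != n)
    msg <- c(msg, "per-window vectors must have equal length")
  if (is.finite(object@periodCv) && object@periodCv < 0)
    msg <- c(msg, "periodCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MethodComparison: noninvasive-to-invasive feature ratios
#'
#' @slot durationRatio positive-duration ratio (noninvasive / invasive).
#' @slot depolSlopeRatio depolarization-slope ratio.
#' @slot repolSlopeRatio repolarization-slope ratio (of magnitudes).
#' @slot periodDifference mean period difference, noninvasive - invasive (s).
#' @seealso [compareMethods()]
#' @export
setClass("MethodComparison",
  representation(durationRatio = "numeric", depolSlopeRatio = "numeric",
                 repolSlopeRatio = "numeric", periodDifference = "numeric"))

setValidity("MethodComparison", function(object) {
  ratios <- c(object@durationRatio, object@depolSlopeRatio,
              object@repolSlopeRatio)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    "all ratios must be positive and finite" else TRUE
})

#' FittedInterface: first-order interface model fitted from paired traces
#'
#' @slot dcGain fitted DC gain (> 0).
#' @slot timeConstant fitted time constant tau in seconds (>= 0).
#' @slot residualRms root-mean-square residual of the fit (V).
#' @seealso [fitRelativeTransfer()]
#' @export
setClass("FittedInterface",
  representation(dcGain = "numeric", timeConstant = "numeric",
                 residualRms = "numeric"))

setValidity("FittedInterface", function(object) {
  msg <- character(0)
  if (object@dcGain <= 0) msg <- c(msg, "dcGain must be > 0")
  if (object@timeConstant < 0) msg <- c(msg, "timeConstant must be >= 0")
  if (length(msg)) msg else TRUE
})
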