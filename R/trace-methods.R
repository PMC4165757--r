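#' @rdname accessors
#' @export
setMethod("samples", "ECGTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "ECGTrace", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setMethod("startTime", "ECGTrace", function(object) object@startTime)

#' @rdname accessors
#' @export
setMethod("traceMetadata", "ECGTrace", function(object) object@metadata)

#' @rdname accessors
#' @export
setMethod("traceTimes", "ECGTrace", function(object) {
  object@startTime + (seq_along(object@samples) - 1L) / object@samplingRate
})

#' @rdname accessors
#' @export
setMethod("traceDuration", "ECGTrace", function(object) {
  length(object@samples) / object@samplingRate
})

setMethod("length", "ECGTrace", function(x) length(x@samples))

setMethod("show", "ECGTrace", function(object) {
  md <- object@metadata
  cat(sprintf("ECGTrace: %d samples at %g Hz (%.2f s)\n",
              length(object@samples), object@samplingRate,
              traceDuration(object)))
  cat(sprintf("  range: [%.3g, %.3g] V\n",
              min(object@samples), max(object@samples)))
  if (length(md)) {
    keys <- c("phenotype", "method")
    for (k in intersect(keys, names(md)))
      cat(sprintf("  %s: %s\n", k, as.character(md[[k]])))
  }
  invisible(NULL)
})

## replace samples, keeping everything else -- the common internal pattern
## for filters and simulators
replaceSamples <- function(trace, newSamples, method = NULL) {
  md <- trace@metadata
  if (!is.null(method)) md$method <- method
  new("ECGTrace", samples = as.numeric(newSamples),
      samplingRate = trace@samplingRate, startTime = trace@startTime,
      metadata = md)
}

#' @rdname accessors
#' @export
setMethod("beatTimes", "BeatSeries", function(object) object@beatTimes)

#' @rdname accessors
#' @export
setMethod("beatPeriods", "BeatSeries", function(object) object@periods)

setMethod("length", "BeatSeries", function(x) length(x@beatTimes))

setMethod("show", "BeatSeries", function(object) {
  cat(sprintf("BeatSeries: %d beats", length(object@beatTimes)))
  if (length(object@periods))
    cat(sprintf(", mean period %.4f s (sd %.4f)",
                mean(object@periods), stats::sd(object@periods)))
  cat("\n")
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("numerator", "TransferFunction", function(object) object@numerator)

#' @rdname accessors
#' @export
setMethod("denominator", "TransferFunction",
          function(object) object@denominator)

setMethod("show", "TransferFunction", function(object) {
  fmt <- function(p) paste(signif(p, 6), collapse = ", ")
  cat("TransferFunction H(s)\n")
  cat("  numerator  (desc s):", fmt(object@numerator), "\n")
  cat("  denominator(desc s):", fmt(object@denominator), "\n")
  cat(sprintf("  DC gain: %.6g\n", evalTransfer(object, 0 + 0i)))
  invisible(NULL)
})

#' Multiply (cascade) two transfer functions
#'
#' @param e1,e2 [TransferFunction-class] objects.
#' @return Their product as a [TransferFunction-class].
#' @export
setMethod("*", signature("TransferFunction", "TransferFunction"),
  function(e1, e2) {
    r <- ratMul(list(num = e1@numerator, den = e1@denominator),
                list(num = e2@numerator, den = e2@denominator))
    TransferFunction(r$num, r$den)
  })

setMethod("show", "WaveformFeatures", function(object) {
  cat("WaveformFeatures (means over", object@nBeats, "beats)\n")
  cat(sprintf("  positive duration:    %.4f s\n", object@positiveDuration))
  cat(sprintf("  depolarization slope: %+.4g V/s\n",
              object@depolarizationSlope))
  cat(sprintf("  repolarization slope: %+.4g V/s\n",
              object@repolarizationSlope))
  cat(sprintf("  peak amplitude:       %.4g V\n", object@peakAmplitude))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("positiveDuration", "WaveformFeatures",
          function(object) object@positiveDuration)

#' @rdname accessors
#' @export
setMethod("depolarizationSlope", "WaveformFeatures",
          function(object) object@depolarizationSlope)

#' @rdname accessors
#' @export
setMethod("repolarizationSlope", "WaveformFeatures",
          function(object) object@repolarizationSlope)

#' @rdname accessors
#' @export
setMethod("peakAmplitude", "WaveformFeatures",
          function(object) object@peakAmplitude)

#' @rdname accessors
#' @export
setMethod("nBeats", "WaveformFeatures", function(object) object@nBeats)

#' @rdname accessors
#' @export
setMethod("amplitudeTrend", "StabilityReport",
          function(object) object@amplitudeTrend)

#' @rdname accessors
#' @export
setMethod("periodCv", "StabilityReport", function(object) object@periodCv)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d windows (%d valid)\n",
              length(object@windowCenters), sum(object@windowValid)))
  cat(sprintf("  amplitude trend: %+.3f %%/min\n",
              100 * object@amplitudeTrend))
  cat(sprintf("  period CV:       %.4f\n", object@periodCv))
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("dcGain", "FittedInterface", function(object) object@dcGain)

#' @rdname accessors
#' @export
setMethod("timeConstant", "FittedInterface",
          function(object) object@timeConstant)

#' @rdname accessors
#' @export
setMethod("residualRms", "FittedInterface", function(object) object@residualRms)

setMethod("show", "FittedInterface", function(object) {
  cat(sprintf("FittedInterface: dcGain = %.4f, tau = %.4g s, residual RMS = %.3g V\n",
              object@dcGain, object@timeConstant, object@residualRms))
  invisible(NULL)
})
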