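#' Accessors for package classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(object) standardGeneric("traceMetadata"))

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setGeneric("traceDuration", function(object) standardGeneric("traceDuration"))

#' @rdname accessors
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))

#' @rdname accessors
#' @export
setGeneric("beatPeriods", function(object) standardGeneric("beatPeriods"))

#' @rdname accessors
#' @export
setGeneric("numerator", function(object) standardGeneric("numerator"))

#' @rdname accessors
#' @export
setGeneric("denominator", function(object) standardGeneric("denominator"))

#' @rdname accessors
#' @export
setGeneric("dcGain", function(object) standardGeneric("dcGain"))

#' @rdname accessors
#' @export
setGeneric("timeConstant", function(object) standardGeneric("timeConstant"))

#' @rdname accessors
#' @export
setGeneric("residualRms", function(object) standardGeneric("residualRms"))

#' @rdname accessors
#' @export
setGeneric("positiveDuration", function(object) standardGeneric("positiveDuration"))

#' @rdname accessors
#' @export
setGeneric("depolarizationSlope",
           function(object) standardGeneric("depolarizationSlope"))

#' @rdname accessors
#' @export
setGeneric("repolarizationSlope",
           function(object) standardGeneric("repolarizationSlope"))

#' @rdname accessors
#' @export
setGeneric("peakAmplitude", function(object) standardGeneric("peakAmplitude"))

#' @rdname accessors
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))

#' @rdname accessors
#' @export
setGeneric("amplitudeTrend", function(object) standardGeneric("amplitudeTrend"))

#' @rdname accessors
#' @export
setGeneric("periodCv", function(object) standardGeneric("periodCv"))

#' Derive the source-to-output transfer function of an electrode model
#'
#' Builds the Laplace-domain voltage divider from the cardiac source through
#' the electrode's interface and bulk impedances into the amplifier load.
#'
#' @param model an electrode model object.
#' @return A [TransferFunction-class].
#' @name electrodeTransfer
NULL

#' @rdname electrodeTransfer
#' @export
setGeneric("needleTransfer", function(model) standardGeneric("needleTransfer"))

#' @rdname electrodeTransfer
#' @export
setGeneric("gainTransfer", function(model) standardGeneric("gainTransfer"))

#' @rdname electrodeTransfer
#' @export
setGeneric("gelledTransfer", function(model) standardGeneric("gelledTransfer"))

#' @rdname bode
#' @export
setGeneric("bode", function(tf, freqs) standardGeneric("bode"))

#' @rdname simulateResponse
#' @export
setGeneric("simulateResponse",
           function(tf, trace) standardGeneric("simulateResponse"))
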