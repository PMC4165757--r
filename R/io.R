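## Trace files are plain delimited text: a '#'-prefixed key/value header
## (sampling_rate_hz, units, phenotype, method, ...), a column-name line,
## then two tab-separated columns time_s, voltage_<unit>.

.unitScale <- c("V" = 1, "mV" = 1e-3, "uV" = 1e-6, "µV" = 1e-6,
                "nV" = 1e-9)

#' Read an ECG trace from a delimited text file
#'
#' Expects the format written by [writeTrace()]: header lines
#' \code{# key: value}, one column-name line, then \code{time_s} and
#' \code{voltage} columns. The voltage unit from the \code{units} header
#' (V, mV, uV/\code{µV}, nV - raw pupal signals are on the order of
#' nanovolts before amplification) is converted to volts. The time column
#' must be uniform to 1e-9 s and consistent with the stated sampling rate;
#' the first offending row is named otherwise.
#'
#' @param path file path.
#' @return An [ECGTrace-class].
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  isHeader <- grepl("^#", lines)
  hdr <- lines[isHeader]
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      key <- trimws(substr(kv, 1L, sep - 1L))
      val <- trimws(substr(kv, sep + 1L, nchar(kv)))
      meta[[key]] <- val
    }
  }
  body <- lines[!isHeader]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("trace file has no data rows: ", path)
  body <- body[-1L]  # column-name line
  n <- length(body)
  parts <- strsplit(body, "[\t ,]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("malformed data row ", bad[1L], " in ", path)
  tm <- as.numeric(vapply(parts, `[`, "", 1L))
  v <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(tm) || anyNA(v))
    stop("non-numeric data at row ",
         which(is.na(tm) | is.na(v))[1L], " in ", path)

  unit <- if (!is.null(meta$units)) meta$units else "V"
  if (!unit %in% names(.unitScale))
    stop("unknown voltage unit '", unit, "' in ", path)
  v <- v * .unitScale[[unit]]

  if (n > 1L) {
    dt <- diff(tm)
    step <- stats::median(dt)
    off <- which(abs(dt - step) > 1e-9)
    if (length(off))
      stop("non-uniform time grid in ", path, ": step at row ", off[1L] + 1L,
           " is ", signif(dt[off[1L]], 6), " s, expected ",
           signif(step, 6), " s")
    fs <- 1 / step
  } else {
    fs <- NA_real_
  }
  if (!is.null(meta$sampling_rate_hz)) {
    fsHdr <- as.numeric(meta$sampling_rate_hz)
    if (is.finite(fs) && abs(fs - fsHdr) > 1e-6 * fsHdr)
      stop("stated sampling_rate_hz (", fsHdr,
           ") disagrees with the time grid (", signif(fs, 8), " Hz) in ", path)
    fs <- fsHdr
  }
  if (!is.finite(fs))
    stop("sampling rate unavailable: single-row file without sampling_rate_hz header")

  keep <- setdiff(names(meta), c("sampling_rate_hz", "units"))
  ECGTrace(v, samplingRate = fs, startTime = if (n) tm[1L] else 0,
           metadata = meta[keep])
}

#' Write an ECG trace to a delimited text file
#'
#' Inverse of [readTrace()]. Formatting is deterministic (fixed significant
#' digits), voltages are written in volts, and scalar metadata entries are
#' embedded in the header so every output records how it was produced.
#' Vector-valued metadata (e.g. the generator's ground-truth beat onsets) is
#' not serialised.
#'
#' @param trace an [ECGTrace-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "ECGTrace"))
  if (length(trace) == 0L) stop("refusing to write a zero-length trace")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", samplingRate(trace)), con)
  writeLines("# units: V", con)
  md <- traceMetadata(trace)
  for (k in names(md)) {
    val <- md[[k]]
    if (length(val) == 1L && (is.character(val) || is.numeric(val)))
      writeLines(sprintf("# %s: %s", k, format(val, digits = 15)), con)
  }
  writeLines("time_s\tvoltage_v", con)
  tm <- traceTimes(trace)
  writeLines(sprintf("%.10f\t%.12e", tm, samples(trace)), con)
  invisible(path)
}

#' Read a synthetic-recording configuration from a YAML file
#'
#' Flat key/value file whose keys mirror the [syntheticConfig()] arguments;
#' beat-shape fields use the keys \code{amplitude}, \code{riseTime},
#' \code{plateauTime}, \code{fallTime}, \code{undershootFraction}. A
#' \code{phenotypeLabel} of CS, NP or SERCA-depleted pulls that preset first
#' and then applies the file's overrides.
#'
#' @param path YAML file path.
#' @return A [SyntheticConfig-class].
#' @export
readSyntheticConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  configFromList(raw)
}

## YAML 1.1 parses unsigned-exponent notation like 2.0e6 as a string;
## coerce anything that R reads as a plain number, and widen integers
normalizeScalars <- function(raw) {
  lapply(raw, function(v) {
    if (is.integer(v)) return(as.numeric(v))
    if (is.character(v) && length(v) == 1L) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) return(num)
    }
    v
  })
}

configFromList <- function(raw) {
  stopifnot(is.list(raw))
  raw <- normalizeScalars(raw)
  raw$phenotypeLabel <- if (!is.null(raw$phenotypeLabel))
    as.character(raw$phenotypeLabel) else raw$phenotypeLabel
  raw$method <- if (!is.null(raw$method)) as.character(raw$method)
    else raw$method
  shapeKeys <- c("amplitude", "riseTime", "plateauTime", "fallTime",
                 "undershootFraction")
  shapeArgs <- raw[intersect(names(raw), shapeKeys)]
  cfgArgs <- raw[setdiff(names(raw), c(shapeKeys, "method"))]
  label <- raw$phenotypeLabel
  if (!is.null(label) && label %in% names(presetHeartRates())) {
    preset <- list(phenotype = label,
                   method = if (!is.null(raw$method)) raw$method
                            else "noninvasive")
    cfgArgs$phenotypeLabel <- NULL
    base <- do.call(phenotypePreset, preset)
    for (nm in names(cfgArgs)) slot(base, nm) <- cfgArgs[[nm]]
    if (length(shapeArgs)) base@beatShape <- do.call(BeatShape, shapeArgs)
    validObject(base)
    return(base)
  }
  if (length(shapeArgs)) cfgArgs$beatShape <- do.call(BeatShape, shapeArgs)
  do.call(syntheticConfig, cfgArgs)
}

#' Read an electrode circuit model from a YAML file
#'
#' Flat key/value file with a \code{type} key (\code{needle}, \code{gelled}
#' or \code{gain}) and component fields named as in the model constructors
#' (\code{cEh}, \code{rEh}, \code{rBody}, \code{rIp}, ...). Missing
#' components take the constructor defaults.
#'
#' @param path YAML file path.
#' @return An electrode model object.
#' @seealso [electrodeModelConstructors]
#' @export
readElectrodeModel <- function(path) {
  raw <- yaml::read_yaml(path)
  type <- raw$type
  raw <- normalizeScalars(raw)
  raw$type <- type
  if (is.null(type)) stop("electrode model file must declare a 'type'")
  raw$type <- NULL
  ctor <- switch(type,
                 needle = NeedleElectrodeModel,
                 gelled = GelledElectrodeModel,
                 gain = ,
                 GaIn = GaInElectrodeModel,
                 stop("unknown electrode model type '", type, "'"))
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown component(s) for ", type, " model: ",
         paste(unknown, collapse = ", "))
  do.call(ctor, raw)
}

## key/value report writer shared by the pipeline subcommands; params are
## embedded so every artifact records its provenance
writeKeyValueReport <- function(values, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params))
    writeLines(sprintf("# %s: %s", k, format(params[[k]], digits = 15)), con)
  for (k in names(values))
    writeLines(sprintf("%s\t%s", k, format(values[[k]], digits = 15)), con)
  invisible(path)
}
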