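#' Run one step of the analysis pipeline
#'
#' Programmatic front-end behind the command-line script shipped at
#' \code{system.file("scripts", "ecg-pipeline.R", package = "pupaECG")}.
#' Each subcommand reads and writes the package's plain-text formats and
#' embeds the full parameter set in its outputs. Parameters are taken from
#' \code{config} (e.g. a list from [yaml::read_yaml()]), overridden by
#' \code{...}; defaults fill the rest. Identical inputs and seeds give
#' byte-identical outputs.
#'
#' Subcommands and their main parameters:
#' \describe{
#'   \item{simulate}{\code{preset} (CS/NP/SERCA-depleted) or
#'     \code{config_file}, \code{method}, \code{duration}, \code{seed},
#'     \code{output}.}
#'   \item{preprocess}{\code{input}, \code{output}, \code{notch_freq} (60),
#'     \code{notch_q} (10), \code{ma_window} (200).}
#'   \item{beats}{\code{input}, \code{output} (beat times),
#'     \code{summary_output} (period summaries), \code{offsets},
#'     \code{min_cycles}.}
#'   \item{features}{\code{input}, \code{output}.}
#'   \item{model}{either \code{needle_trace} + \code{gain_trace} (fit a
#'     first-order interface from paired recordings) or
#'     \code{needle_model} + \code{gain_model} files (derive H(s) from
#'     circuits); \code{output}.}
#'   \item{bode}{\code{needle_model}, \code{gain_model}, \code{fmin},
#'     \code{fmax}, \code{n_freqs}, \code{output}.}
#'   \item{stability}{\code{input}, \code{window} (60 s), \code{output}.}
#'   \item{compare}{\code{invasive}, \code{noninvasive}, \code{output}.}
#' }
#'
#' @param command one of \code{simulate}, \code{preprocess}, \code{beats},
#'   \code{features}, \code{model}, \code{bode}, \code{stability},
#'   \code{compare}.
#' @param config named list of parameters (a parsed config file).
#' @param ... parameter overrides, highest precedence.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
runPipeline <- function(command, config = list(), ...) {
  command <- match.arg(command, c("simulate", "preprocess", "beats",
                                  "features", "model", "bode", "stability",
                                  "compare"))
  p <- config
  dots <- list(...)
  p[names(dots)] <- dots
  get1 <- function(name, default = NULL) {
    if (!is.null(p[[name]])) p[[name]] else default
  }
  need <- function(name) {
    v <- p[[name]]
    if (is.null(v)) stop("subcommand '", command, "' requires parameter '",
                         name, "'")
    v
  }
  out <- switch(command,
    simulate = {
      cfg <- if (!is.null(p$config_file)) readSyntheticConfig(p$config_file)
        else phenotypePreset(get1("preset", "CS"),
                             method = get1("method", "noninvasive"),
                             duration = as.numeric(get1("duration", 60)),
                             seed = as.numeric(get1("seed", 1)))
      tr <- generateTrace(cfg)
      path <- need("output")
      writeTrace(tr, path)
      message("simulate: wrote ", length(tr), " samples to ", path)
      list(trace = path)
    },
    preprocess = {
      tr <- readTrace(need("input"))
      clean <- preprocess(tr,
                          notchFreq = as.numeric(get1("notch_freq", 60)),
                          notchQ = as.numeric(get1("notch_q", 10)),
                          maWindow = as.numeric(get1("ma_window", 200)))
      path <- need("output")
      writeTrace(clean, path)
      message("preprocess: wrote ", path)
      list(trace = path)
    },
    beats = {
      tr <- readTrace(need("input"))
      beats <- detectBeats(tr,
        thresholdFraction = as.numeric(get1("threshold_fraction", 0.5)),
        refractory = as.numeric(get1("refractory", 0.1)))
      path <- need("output")
      con <- file(path, "w")
      writeLines(c(sprintf("# source: %s", p$input),
                   sprintf("# threshold_fraction: %g",
                           as.numeric(get1("threshold_fraction", 0.5))),
                   "beat_time_s"), con)
      writeLines(sprintf("%.6f", beatTimes(beats)), con)
      close(con)
      paths <- list(beats = path)
      sumPath <- get1("summary_output")
      if (!is.null(sumPath)) {
        offs <- as.numeric(get1("offsets", c(10, 100, 1000)))
        sm <- periodSummary(beats, offsets = offs,
                            minCycles = as.numeric(get1("min_cycles", 20)))
        con <- file(sumPath, "w")
        writeLines(c(sprintf("# source: %s", p$input),
                     "offset\tn\tmean_s\tsd_s\tvalid"), con)
        writeLines(sprintf("%g\t%d\t%.6f\t%.6f\t%s", sm$offset, sm$n_cycles,
                           sm$mean_period, sm$sd_period, sm$valid), con)
        close(con)
        paths$summary <- sumPath
      }
      message("beats: ", length(beats), " beats detected")
      paths
    },
    features = {
      tr <- readTrace(need("input"))
      beats <- detectBeats(tr)
      ft <- extractFeatures(tr, beats)
      path <- need("output")
      writeKeyValueReport(
        list(positive_duration_s = positiveDuration(ft),
             depolarization_slope_v_per_s = depolarizationSlope(ft),
             repolarization_slope_v_per_s = repolarizationSlope(ft),
             peak_amplitude_v = peakAmplitude(ft),
             n_beats = nBeats(ft)),
        path, params = list(input = p$input))
      message("features: ", nBeats(ft), " beats used")
      list(features = path)
    },
    model = {
      path <- need("output")
      if (!is.null(p$needle_trace) && !is.null(p$gain_trace)) {
        fit <- fitRelativeTransfer(readTrace(p$needle_trace),
                                   readTrace(p$gain_trace))
        writeKeyValueReport(
          list(dc_gain = dcGain(fit), time_constant_s = timeConstant(fit),
               residual_rms_v = residualRms(fit)),
          path, params = p[c("needle_trace", "gain_trace")])
      } else {
        H <- relativeTransfer(
          gainTransfer(readElectrodeModel(need("gain_model"))),
          needleTransfer(readElectrodeModel(need("needle_model"))))
        writeKeyValueReport(
          list(numerator = paste(numerator(H), collapse = " "),
               denominator = paste(denominator(H), collapse = " ")),
          path, params = p[c("needle_model", "gain_model")])
      }
      message("model: wrote ", path)
      list(model = path)
    },
    bode = {
      H <- relativeTransfer(
        gainTransfer(readElectrodeModel(need("gain_model"))),
        needleTransfer(readElectrodeModel(need("needle_model"))))
      freqs <- 10^seq(log10(as.numeric(get1("fmin", 0.1))),
                      log10(as.numeric(get1("fmax", 1000))),
                      length.out = as.numeric(get1("n_freqs", 200)))
      path <- need("output")
      writeBodeTable(bode(H, freqs), path)
      message("bode: wrote ", path)
      list(bode = path)
    },
    stability = {
      tr <- readTrace(need("input"))
      rep <- stabilityAnalysis(tr, window = as.numeric(get1("window", 60)))
      path <- need("output")
      writeKeyValueReport(
        list(amplitude_trend_per_min = amplitudeTrend(rep),
             period_cv = periodCv(rep),
             n_windows = length(rep@windowCenters),
             n_valid_windows = sum(rep@windowValid)),
        path, params = list(input = p$input,
                            window_s = as.numeric(get1("window", 60))))
      message("stability: wrote ", path)
      list(stability = path)
    },
    compare = {
      trInv <- readTrace(need("invasive"))
      trNon <- readTrace(need("noninvasive"))
      bInv <- detectBeats(trInv)
      bNon <- detectBeats(trNon)
      cmp <- compareMethods(extractFeatures(trInv, bInv),
                            extractFeatures(trNon, bNon), bInv, bNon)
      path <- need("output")
      writeKeyValueReport(
        list(duration_ratio = cmp@durationRatio,
             depol_slope_ratio = cmp@depolSlopeRatio,
             repol_slope_ratio = cmp@repolSlopeRatio,
             period_difference_s = cmp@periodDifference),
        path, params = p[c("invasive", "noninvasive")])
      message("compare: wrote ", path)
      list(comparison = path)
    })
  invisible(out)
}
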