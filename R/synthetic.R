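#' Sample one beat template from a BeatShape
#'
#' Renders the piecewise-linear beat (rise, plateau, fall, optional
#' undershoot) on the sample grid. First and last samples sit at the 0 V
#' baseline. When \code{undershootFraction > 0} the undershoot is a triangle
#' of total duration \code{riseTime + fallTime} with its apex at
#' \code{-undershootFraction * amplitude}.
#'
#' @param shape a [BeatShape-class].
#' @param samplingRate sampling frequency in Hz (> 0).
#' @return Numeric vector of voltages, one beat long.
#' @examples
#' tpl <- makeBeatTemplate(BeatShape(), 2604)
#' max(diff(tpl)) * 2604  # rising-edge slope in V/s
#' @export
makeBeatTemplate <- function(shape, samplingRate) {
  if (!is.numeric(samplingRate) || length(samplingRate) != 1L ||
      !is.finite(samplingRate) || samplingRate <= 0)
    stop("samplingRate must be a single positive number")
  validObject(shape)
  A <- shape@amplitude
  r <- shape@riseTime
  p <- shape@plateauTime
  f <- shape@fallTime
  uf <- shape@undershootFraction
  u <- if (uf > 0) r + f else 0
  total <- r + p + f + u
  n <- floor(total * samplingRate + 1e-9) + 1L
  t <- (seq_len(n) - 1L) / samplingRate
  v <- numeric(n)
  if (r > 0) {
    i <- t < r
    v[i] <- A * t[i] / r
  }
  i <- t >= r & t < r + p
  v[i] <- A
  if (f > 0) {
    i <- t >= r + p & t < r + p + f
    v[i] <- A * (1 - (t[i] - r - p) / f)
  }
  if (u > 0) {
    i <- t >= r + p + f & t < total
    tu <- t[i] - (r + p + f)
    v[i] <- -uf * A * (1 - abs(tu - u / 2) / (u / 2))
  }
  v[n] <- 0
  v
}

#' Build a synthetic recording configuration
#'
#' Collects every knob of the generator into a validated
#' [SyntheticConfig-class]. All defaults describe a clean noninvasive-style
#' recording; see [phenotypePreset()] for the study-style presets.
#'
#' @param heartRate mean heart rate (Hz).
#' @param duration recording duration (s).
#' @param samplingRate sampling frequency (Hz), default 2604.
#' @param beatShape a [BeatShape-class].
#' @param powerlineAmplitude,powerlineFreq mains interference (V, Hz).
#' @param whiteNoiseSd white noise sd (V).
#' @param baselineWanderAmplitude,baselineWanderFreq slow baseline
#'   oscillation (V, Hz).
#' @param periodJitterSd per-beat period jitter sd (s).
#' @param amplitudeDriftRate fractional amplitude loss per minute; beat
#'   amplitude follows \eqn{(1 - r)^{t/60}}.
#' @param periodDriftRate fractional period lengthening per minute (linear).
#' @param amplifierEnabled,amplifierGainDb,amplifierLowCut,amplifierHighCut
#'   optional AC-coupled amplifier front-end stage (off by default): a
#'   first-order band-pass between the two corner frequencies plus gain.
#' @param seed integer RNG seed.
#' @param phenotypeLabel "CS", "NP", "SERCA-depleted" or "custom".
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(heartRate = 2, duration = 60, samplingRate = 2604,
                            beatShape = BeatShape(),
                            powerlineAmplitude = 0, powerlineFreq = 60,
                            whiteNoiseSd = 0,
                            baselineWanderAmplitude = 0,
                            baselineWanderFreq = 0.2,
                            periodJitterSd = 0,
                            amplitudeDriftRate = 0, periodDriftRate = 0,
                            amplifierEnabled = FALSE, amplifierGainDb = 0,
                            amplifierLowCut = 5, amplifierHighCut = 10000,
                            seed = 1L, phenotypeLabel = "custom") {
  new("SyntheticConfig", heartRate = heartRate, duration = duration,
      samplingRate = samplingRate, beatShape = beatShape,
      powerlineAmplitude = powerlineAmplitude, powerlineFreq = powerlineFreq,
      whiteNoiseSd = whiteNoiseSd,
      baselineWanderAmplitude = baselineWanderAmplitude,
      baselineWanderFreq = baselineWanderFreq,
      periodJitterSd = periodJitterSd,
      amplitudeDriftRate = amplitudeDriftRate,
      periodDriftRate = periodDriftRate,
      amplifierEnabled = amplifierEnabled,
      amplifierGainDb = amplifierGainDb,
      amplifierLowCut = amplifierLowCut,
      amplifierHighCut = amplifierHighCut,
      seed = as.numeric(seed), phenotypeLabel = phenotypeLabel)
}

#' Phenotype and recording-method presets
#'
#' Heart-rate presets for the three fly lines studied with this pipeline:
#' wild-type Canton-S (CS) beats fastest, the NP1029-GAL4 driver control (NP)
#' is intermediate, and SERCA-depleted hearts (RNAi knockdown of the
#' sarcoendoplasmic reticulum Ca2+-ATPase) beat slowest. The numeric rates
#' (CS 4 Hz, NP 3 Hz, SERCA-depleted 1.5 Hz) are illustrative defaults chosen
#' to honour that ordering; they are not literature values. The
#' \code{method} argument controls recording stability: \code{"invasive"}
#' recordings drift in amplitude and period over minutes, while
#' \code{"noninvasive"} (GaIn surface electrode) recordings are stationary.
#'
#' @param phenotype "CS", "NP" or "SERCA-depleted".
#' @param method "noninvasive" (stationary) or "invasive" (drifting).
#' @param duration recording duration (s).
#' @param seed RNG seed.
#' @param ... further arguments passed to [syntheticConfig()].
#' @return A [SyntheticConfig-class].
#' @examples
#' cfg <- phenotypePreset("SERCA-depleted", method = "invasive",
#'                        duration = 120, seed = 7)
#' @export
phenotypePreset <- function(phenotype = c("CS", "NP", "SERCA-depleted"),
                            method = c("noninvasive", "invasive"),
                            duration = 60, seed = 1L, ...) {
  phenotype <- match.arg(phenotype)
  method <- match.arg(method)
  rate <- presetHeartRates()[[phenotype]]
  drift <- method == "invasive"
  args <- list(
    heartRate = rate, duration = duration, seed = seed,
    phenotypeLabel = phenotype,
    whiteNoiseSd = 0.05e-3, powerlineAmplitude = 0.2e-3,
    baselineWanderAmplitude = 0.1e-3, baselineWanderFreq = 0.2,
    periodJitterSd = 0.010,
    amplitudeDriftRate = if (drift) 0.03 else 0,
    periodDriftRate = if (drift) 0.02 else 0)
  extra <- list(...)
  args[names(extra)] <- extra
  cfg <- do.call(syntheticConfig, args)
  cfg
}

#' @rdname phenotypePreset
#' @return \code{presetHeartRates} returns the named preset heart-rate table
#'   (Hz).
#' @export
presetHeartRates <- function() {
  c("CS" = 4, "NP" = 3, "SERCA-depleted" = 1.5)
}

## run code with a seeded, isolated RNG stream; the caller's .Random.seed
## is untouched
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic pupal ECG trace
#'
#' Lays down a pulse train of [makeBeatTemplate()] beats at the configured
#' heart rate, with per-beat normal period jitter (truncated so consecutive
#' beats never overlap), multiplicative amplitude drift
#' \eqn{(1-r)^{t/60}}, linear-in-time period drift, then adds powerline
#' interference, white noise and baseline wander. Identical configurations
#' produce bitwise-identical traces.
#'
#' The true beat onset times, peak times and per-beat amplitudes used during
#' construction are recorded in the trace metadata (\code{beatOnsets},
#' \code{beatPeakTimes}, \code{beatAmplitudes}) so downstream detectors can
#' be scored against ground truth.
#'
#' @param config a [SyntheticConfig-class].
#' @return An [ECGTrace-class] with \code{method = "simulated"} metadata.
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 10))
#' length(traceMetadata(tr)$beatOnsets)  # 20 beats
#' @export
generateTrace <- function(config) {
  validObject(config)
  fs <- config@samplingRate
  dur <- config@duration
  template <- makeBeatTemplate(config@beatShape, fs)
  beatWidth <- (length(template) - 1L) / fs
  basePeriod <- 1 / config@heartRate
  if (basePeriod < beatWidth)
    stop("beats overlap: heart period ", signif(basePeriod, 4),
         " s is shorter than the beat width ", signif(beatWidth, 4), " s")

  withLocalSeed(config@seed, {
    ## beat bookkeeping
    onsets <- numeric(0)
    amps <- numeric(0)
    t <- 0
    while (t < dur) {
      onsets <- c(onsets, t)
      amps <- c(amps, (1 - config@amplitudeDriftRate)^(t / 60))
      period <- basePeriod * (1 + config@periodDriftRate * (t / 60))
      if (config@periodJitterSd > 0)
        period <- period + stats::rnorm(1L, 0, config@periodJitterSd)
      period <- max(period, beatWidth)  # truncate: periods stay positive
      t <- t + period
    }

    n <- round(dur * fs)
    x <- numeric(n)
    lt <- length(template)
    for (k in seq_along(onsets)) {
      i0 <- round(onsets[k] * fs) + 1L
      i1 <- min(i0 + lt - 1L, n)
      if (i0 > n) break
      x[i0:i1] <- x[i0:i1] + amps[k] * template[seq_len(i1 - i0 + 1L)]
    }
    tt <- (seq_len(n) - 1L) / fs
    if (config@baselineWanderAmplitude > 0)
      x <- x + config@baselineWanderAmplitude *
        sin(2 * pi * config@baselineWanderFreq * tt)
    if (config@whiteNoiseSd > 0)
      x <- x + stats::rnorm(n, 0, config@whiteNoiseSd)
    if (config@powerlineAmplitude != 0)
      x <- x + config@powerlineAmplitude *
        sin(2 * pi * config@powerlineFreq * tt)

    if (config@amplifierEnabled)
      x <- applyAmplifier(x, fs, config@amplifierGainDb,
                          config@amplifierLowCut, config@amplifierHighCut)

    shape <- config@beatShape
    ECGTrace(x, samplingRate = fs, startTime = 0, metadata = list(
      phenotype = config@phenotypeLabel,
      method = "simulated",
      beatOnsets = onsets,
      beatPeakTimes = onsets + shape@riseTime + shape@plateauTime / 2,
      beatAmplitudes = amps * shape@amplitude,
      config = list(heartRate = config@heartRate, duration = dur,
                    samplingRate = fs, seed = config@seed,
                    amplitudeDriftRate = config@amplitudeDriftRate,
                    periodDriftRate = config@periodDriftRate,
                    periodJitterSd = config@periodJitterSd)))
  })
}

## AC-coupled amplifier front-end: first-order high-pass at lowCut cascaded
## with first-order low-pass at highCut, plus flat gain.
applyAmplifier <- function(x, fs, gainDb, lowCut, highCut) {
  g <- 10^(gainDb / 20)
  wl <- 2 * pi * lowCut
  wh <- 2 * pi * highCut
  if (highCut >= fs / 2)
    warning("amplifier high corner at ", highCut,
            " Hz is at or above Nyquist; low-pass stage is nearly transparent")
  hp <- ratBilinear(c(1, 0), c(1, wl), fs)
  lp <- ratBilinear(wh, c(1, wh), fs)
  y <- as.numeric(signal::filter(hp$b, hp$a, x))
  y <- as.numeric(signal::filter(lp$b, lp$a, y))
  g * y
}

#' Add powerline interference to a trace
#'
#' Returns a copy of the trace with \code{amplitude * sin(2 pi freq t)}
#' added; the input is unmodified.
#'
#' @param trace an [ECGTrace-class].
#' @param amplitude sinusoid amplitude (V).
#' @param freq sinusoid frequency (Hz); must be below Nyquist.
#' @return A new [ECGTrace-class].
#' @export
addPowerline <- function(trace, amplitude, freq = 60) {
  stopifnot(is(trace, "ECGTrace"))
  if (freq >= samplingRate(trace) / 2)
    stop("powerline frequency ", freq,
         " Hz is at or above Nyquist for this trace")
  if (amplitude == 0) return(trace)
  t <- traceTimes(trace)
  replaceSamples(trace, samples(trace) + amplitude * sin(2 * pi * freq * t))
}
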