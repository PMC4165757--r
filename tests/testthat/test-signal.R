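test_that("notch filter hits 60 Hz with the designed quality factor", {
  fs <- 2604
  co <- notchDesign(60, 10, fs)
  resp <- function(f) {
    z <- exp(1i * 2 * pi * f / fs)
    abs((co$b[1] + co$b[2] / z + co$b[3] / z^2) /
          (co$a[1] + co$a[2] / z + co$a[3] / z^2))
  }

  # magnitude minimum exactly at 60 Hz on a 0.01 Hz grid
  grid <- seq(40, 80, by = 0.01)
  mags <- vapply(grid, resp, 1)
  expect_identical(grid[which.min(mags)], 60)

  # -3 dB rejection bandwidth gives Q = 10 within 2%
  inBand <- grid[mags <= 1 / sqrt(2)]
  q <- 60 / (max(inBand) - min(inBand))
  expect_lt(abs(q - 10) / 10, 0.02)

  # unity gain at DC and Nyquist
  expect_lt(abs(resp(0) - 1), 1e-9)
  expect_lt(abs(resp(fs / 2) - 1), 1e-9)

  # steady 60 Hz tone attenuated by at least 30 dB after the transient
  t <- (0:(3 * fs - 1)) / fs
  tone <- ECGTrace(sin(2 * pi * 60 * t), fs)
  y <- samples(notchFilter(tone))[(fs + 1):(3 * fs)]
  atten <- 20 * log10(sqrt(mean(y^2)) / sqrt(0.5))
  expect_lt(atten, -30)

  # DC input unchanged in steady state (after the notch transient decays)
  dc <- ECGTrace(rep(2e-3, 3 * fs), fs)
  expect_lt(max(abs(samples(notchFilter(dc))[(2 * fs):(3 * fs)] - 2e-3)),
            1e-9)

  expect_error(notchFilter(dc, centerFreq = 1302), "Nyquist")
  expect_error(notchDesign(60, -1, fs), "quality")
})

test_that("moving average is centred, variance-reducing, and length-preserving", {
  fs <- 1000
  const <- ECGTrace(rep(3e-3, 2000), fs)
  expect_equal(samples(movingAverage(const, 200)), rep(3e-3, 2000))

  # unit impulse spreads into exactly window samples of 1/window
  x <- numeric(2001); x[1000] <- 1
  y <- samples(movingAverage(ECGTrace(x, fs), 200))
  hits <- which(abs(y - 1 / 200) < 1e-12)
  expect_length(hits, 200L)
  expect_true(all(diff(hits) == 1))
  expect_length(y, 2001L)

  # white-noise sd shrinks by sqrt(window)
  set.seed(5)
  noise <- ECGTrace(rnorm(1e5, sd = 1e-3), fs)
  smoothed <- samples(movingAverage(noise, 200))
  interior <- smoothed[200:(1e5 - 200)]
  expect_lt(abs(sd(interior) - 1e-3 / sqrt(200)) / (1e-3 / sqrt(200)), 0.10)

  expect_error(movingAverage(ECGTrace(1:10 * 1e-3, fs), 11), "window")
})

test_that("preprocessing is linear, time-invariant and removes mains power", {
  fs <- 2604
  cfg <- cleanConfig(heartRate = 2, duration = 10)
  tr <- generateTrace(cfg)

  # all-zero in, all-zero out
  zero <- ECGTrace(numeric(fs * 2), fs)
  expect_true(all(samples(preprocess(zero)) == 0))

  # linearity
  t <- traceTimes(tr)
  other <- ECGTrace(1e-3 * sin(2 * pi * 3 * t), fs)
  lhs <- samples(preprocess(ECGTrace(samples(tr) + samples(other), fs)))
  rhs <- samples(preprocess(tr)) + samples(preprocess(other))
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # time invariance on interior samples: shifting the input shifts the output
  shift <- 500L
  xs <- c(numeric(shift), samples(tr))
  ys <- samples(preprocess(ECGTrace(xs, fs)))
  y0 <- samples(preprocess(tr))
  sel <- (shift + 300):(length(y0) - 300)
  expect_lt(max(abs(ys[sel + shift][1:1000] - y0[sel][1:1000])), 1e-12)

  # 59-61 Hz band power reduced to under 1% of its contaminated value
  sigRms <- sqrt(mean(samples(tr)^2))
  dirty <- addPowerline(tr, sqrt(2) * sigRms, 60)
  bandPower <- function(x) {
    n <- length(x)
    spec <- Mod(stats::fft(x))^2 / n
    f <- (seq_len(n) - 1) * fs / n
    sum(spec[f >= 59 & f <= 61])
  }
  cleaned <- preprocess(dirty)
  expect_lt(bandPower(samples(cleaned)) / bandPower(samples(dirty)), 0.01)
})

test_that("beat detection recovers the generator's onsets", {
  # all-zero trace: no beats, no error
  empty <- detectBeats(ECGTrace(numeric(1000), 1000))
  expect_length(empty, 0L)

  # noise-free 2 Hz train over 10 s: 20 beats, every period within a sample
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 10))
  beats <- detectBeats(tr)
  expect_length(beats, 20L)
  expect_true(all(abs(beatPeriods(beats) - 0.5) <= 1 / samplingRate(tr)))

  # equal-RMS 60 Hz contamination, preprocessed: identical beat count
  sigRms <- sqrt(mean(samples(tr)^2))
  dirty <- addPowerline(tr, sqrt(2) * sigRms, 60)
  expect_length(detectBeats(preprocess(dirty)), 20L)

  expect_error(detectBeats(tr, thresholdFraction = 1.2), "thresholdFraction")
})

test_that("beat counts stay calibrated across physiological rates", {
  for (rate in c(0.5, 1, 2, 3.5, 5)) {
    dur <- 20
    tr <- generateTrace(cleanConfig(heartRate = rate, duration = dur))
    n <- length(detectBeats(tr))
    expect_lte(abs(n - floor(dur * rate)), 1)
  }
})

test_that("period estimation is unbiased over repeated jittered trains", {
  # many short trains; the pooled period estimate must sit within
  # 3 standard errors of the truth
  est <- c()
  for (seed in 1:60) {
    tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 12,
                                        samplingRate = 500,
                                        beatShape = standardShape(),
                                        periodJitterSd = 0.010, seed = seed))
    est <- c(est, beatPeriods(detectBeats(tr)))
  }
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 3 * se)

  # jittered periods show the injected dispersion: sample sd of n = 20
  # within the 99% chi-square interval
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 15,
                                  periodJitterSd = 0.010, seed = 9))
  s20 <- sd(beatPeriods(detectBeats(tr))[1:20])
  lims <- sqrt(qchisq(c(0.005, 0.995), df = 19) / 19) * 0.010
  expect_gt(s20, lims[1])
  expect_lt(s20, lims[2])
})

test_that("period summaries follow the offset protocol", {
  # perfectly periodic beats
  beats <- BeatSeries(seq(0, 59.5, by = 0.5))
  sm <- periodSummary(beats, offsets = c(10, 100, 1000))
  expect_identical(sm$valid, c(TRUE, FALSE, FALSE))
  expect_equal(sm$mean_period[1], 0.5)
  expect_equal(sm$sd_period[1], 0)
  expect_identical(sm$n_cycles[1], 20L)

  # a 15 s recording only supports the 10 s offset
  short <- BeatSeries(seq(0, 15, by = 0.4))
  sm2 <- periodSummary(short)
  expect_false(any(sm2$valid[2:3]))

  # summaries start at the first beat at or after the offset
  sm3 <- periodSummary(beats, offsets = 10.2, minCycles = 5)
  expect_equal(sm3$mean_period, 0.5)
  expect_identical(sm3$n_cycles, 5L)
})

test_that("stability analysis separates drifting from stationary recordings", {
  stationary <- generateTrace(cleanConfig(heartRate = 2, duration = 240,
                                          periodJitterSd = 0.010, seed = 21))
  srep <- stabilityAnalysis(stationary)
  expect_lt(abs(amplitudeTrend(srep)), 0.005)

  drifting <- generateTrace(cleanConfig(heartRate = 2, duration = 240,
                                        periodJitterSd = 0.010,
                                        amplitudeDriftRate = 0.03,
                                        periodDriftRate = 0.02, seed = 21))
  drep <- stabilityAnalysis(drifting)
  expect_lt(abs(amplitudeTrend(drep) - (-0.03)) / 0.03, 0.20)
  expect_gt(periodCv(drep), periodCv(srep))

  expect_error(stabilityAnalysis(generateTrace(cleanConfig(duration = 30))),
               "two windows")
})
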