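test_that("features recover the analytic trapezoid geometry", {
  fs <- 2604
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 10))
  ft <- extractFeatures(tr, detectBeats(tr))

  # positive duration: rise + plateau + fall = 60 ms within 2 samples
  expect_lt(abs(positiveDuration(ft) - 0.060), 2 / fs)

  # depolarization slope: 1 mV / 10 ms = 0.1 V/s within 5%
  expect_lt(abs(depolarizationSlope(ft) - 0.1) / 0.1, 0.05)

  # repolarization slope: -1 mV / 20 ms = -0.05 V/s within 5%
  expect_lt(abs(repolarizationSlope(ft) + 0.05) / 0.05, 0.05)
  expect_identical(nBeats(ft), 20L)

  # symmetric beat: slope magnitudes match within 1%
  sym <- generateTrace(syntheticConfig(
    heartRate = 2, duration = 10,
    beatShape = BeatShape(riseTime = 0.015, plateauTime = 0.02,
                          fallTime = 0.015)))
  fsym <- extractFeatures(sym, detectBeats(sym))
  expect_lt(abs(depolarizationSlope(fsym) + repolarizationSlope(fsym)) /
              depolarizationSlope(fsym), 0.01)
})

test_that("features scale equivariantly with trace amplitude", {
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 10))
  k <- 3.7
  scaled <- ECGTrace(k * samples(tr), samplingRate(tr),
                     metadata = traceMetadata(tr))
  f1 <- extractFeatures(tr, detectBeats(tr))
  f2 <- extractFeatures(scaled, detectBeats(scaled))
  expect_equal(positiveDuration(f2), positiveDuration(f1))
  expect_equal(depolarizationSlope(f2), k * depolarizationSlope(f1),
               tolerance = 1e-9)
  expect_equal(repolarizationSlope(f2), k * repolarizationSlope(f1),
               tolerance = 1e-9)
  expect_equal(peakAmplitude(f2), k * peakAmplitude(f1), tolerance = 1e-9)
})

test_that("low-pass filtering widens beats and flattens slopes monotonically", {
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 10))
  f0 <- extractFeatures(tr, detectBeats(tr))
  taus <- c(0.002, 0.005, 0.010, 0.020)
  durs <- numeric(0); deps <- numeric(0); reps <- numeric(0)
  for (tau in taus) {
    sim <- simulateResponse(TransferFunction(1, c(tau, 1)), tr)
    ft <- extractFeatures(sim, detectBeats(sim))
    durs <- c(durs, positiveDuration(ft))
    deps <- c(deps, depolarizationSlope(ft))
    reps <- c(reps, abs(repolarizationSlope(ft)))
  }
  expect_true(all(durs > positiveDuration(f0)))
  expect_true(all(deps < depolarizationSlope(f0)))
  expect_true(all(reps < abs(repolarizationSlope(f0))))
  # monotone in tau
  expect_true(all(diff(durs) >= 0))
  expect_true(all(diff(deps) <= 0))
  expect_true(all(diff(reps) <= 0))
})

test_that("method comparison reports ratios and period agreement", {
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 10))
  bInv <- detectBeats(tr)
  fInv <- extractFeatures(tr, bInv)

  # identical inputs: unit ratios, zero period difference
  same <- compareMethods(fInv, fInv, bInv, bInv)
  expect_equal(same@durationRatio, 1)
  expect_equal(same@depolSlopeRatio, 1)
  expect_equal(same@repolSlopeRatio, 1)
  expect_equal(same@periodDifference, 0)

  # noninvasive = low-pass image of invasive
  sim <- simulateResponse(TransferFunction(0.9, c(0.005, 1)), tr)
  bNon <- detectBeats(sim)
  cmp <- compareMethods(fInv, extractFeatures(sim, bNon), bInv, bNon)
  expect_gt(cmp@durationRatio, 1)
  expect_lt(cmp@depolSlopeRatio, 1)
  expect_lt(cmp@repolSlopeRatio, 1)
  expect_lt(abs(cmp@periodDifference), 2 / samplingRate(tr))

  # hand arithmetic on fixed feature tuples
  fa <- new("WaveformFeatures", positiveDuration = 0.06,
            depolarizationSlope = 0.10, repolarizationSlope = -0.05,
            peakAmplitude = 1e-3, nBeats = 10L)
  fb <- new("WaveformFeatures", positiveDuration = 0.09,
            depolarizationSlope = 0.08, repolarizationSlope = -0.04,
            peakAmplitude = 0.9e-3, nBeats = 10L)
  b <- BeatSeries(c(0, 0.5, 1))
  out <- compareMethods(fa, fb, b, b)
  expect_equal(out@durationRatio, 0.09 / 0.06)
  expect_equal(out@depolSlopeRatio, 0.08 / 0.10)
  expect_equal(out@repolSlopeRatio, 0.04 / 0.05)
})

test_that("first-order interface fit recovers generating parameters", {
  tr <- generateTrace(cleanConfig(heartRate = 2, duration = 8))

  # noise-free recovery across a 3x3 grid within 5%
  for (g in c(0.6, 0.8, 1.0)) {
    for (tau in c(0.002, 0.005, 0.010)) {
      vg <- simulateResponse(TransferFunction(g, c(tau, 1)), tr)
      fit <- fitRelativeTransfer(tr, vg)
      expect_lt(abs(dcGain(fit) - g) / g, 0.05)
      expect_lt(abs(timeConstant(fit) - tau) / tau, 0.05)
    }
  }

  # identity pair: unit gain, negligible time constant
  idFit <- fitRelativeTransfer(tr, tr)
  expect_lt(abs(dcGain(idFit) - 1), 0.01)
  expect_lte(timeConstant(idFit), 1 / samplingRate(tr))

  # 40 dB SNR: parameters within 10%, residual within twice the noise sd
  vg <- simulateResponse(TransferFunction(0.8, c(0.005, 1)), tr)
  noiseSd <- sqrt(mean(samples(vg)^2)) / 100
  set.seed(3)
  noisy <- ECGTrace(samples(vg) + rnorm(length(vg), sd = noiseSd),
                    samplingRate(vg))
  fitN <- fitRelativeTransfer(tr, noisy)
  expect_lt(abs(dcGain(fitN) - 0.8) / 0.8, 0.10)
  expect_lt(abs(timeConstant(fitN) - 0.005) / 0.005, 0.10)
  expect_lt(residualRms(fitN), 2 * noiseSd)

  # degenerate inputs
  flat <- ECGTrace(rep(1e-3, length(tr)), samplingRate(tr))
  expect_error(fitRelativeTransfer(flat, flat), "zero-variance")
  shorter <- ECGTrace(samples(tr)[1:100], samplingRate(tr))
  expect_error(fitRelativeTransfer(tr, shorter), "equal length")
})
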