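test_that("Nernst potential matches the closed form and its symmetries", {
  # equal activities
  expect_identical(nernstPotential(298.15, 1, 0.1, 0.1), 0)

  # one decade at 25 C for a monovalent ion: (RT/F) ln 10
  expect_lt(abs(nernstPotential(298.15, 1, 10, 1) - 0.05916), 1e-4)

  # antisymmetry under swapping the compartments
  a <- nernstPotential(310, 2, 0.14, 0.01)
  b <- nernstPotential(310, 2, 0.01, 0.14)
  expect_equal(a, -b)

  # valence scaling
  expect_equal(nernstPotential(298.15, 2, 10, 1),
               nernstPotential(298.15, 1, 10, 1) / 2)

  expect_error(nernstPotential(-1, 1, 1, 1), "temperature")
  expect_error(nernstPotential(298, 0, 1, 1), "valence")
  expect_error(nernstPotential(298, 1, 0, 1), "concentrations")
})

test_that("electrode transfer functions reduce to resistive dividers at DC", {
  # needle: zero capacitances -> pure divider at every frequency
  m <- NeedleElectrodeModel(cEh = 0, rEh = 2e4, rBody = 3e4,
                            rLoad = 1e6, cLoad = 0)
  tf <- needleTransfer(m)
  expected <- 1e6 / (1e6 + 2e4 + 3e4)
  for (f in c(0, 1, 100, 1000))
    expect_equal(Mod(evalAt(tf, f)), expected, tolerance = 1e-12)

  # GaIn: same resistive-divider limit
  g <- GaInElectrodeModel(rIp = 4e5, cIp = 0, rSeries = 1e5,
                          rLoad = 1e6, cLoad = 0)
  expect_equal(Mod(evalAt(gainTransfer(g), 0)),
               1e6 / (1e6 + 1e5 + 4e5), tolerance = 1e-12)

  # near-short interface: unity transfer at all frequencies
  s <- NeedleElectrodeModel(cEh = 0, rEh = 1e-6, rBody = 1e-6,
                            rLoad = 1e6, cLoad = 0)
  expect_equal(Mod(evalAt(needleTransfer(s), 500)), 1, tolerance = 1e-9)

  expect_error(NeedleElectrodeModel(rEh = -1), "resistances")
  expect_error(GaInElectrodeModel(cIp = -1e-9), "capacitances")
})

test_that("rational evaluation agrees with complex nodal arithmetic", {
  set.seed(11)
  for (k in 1:20) {
    mN <- NeedleElectrodeModel(cEh = runif(1, 0, 1e-7),
                               rEh = 10^runif(1, 3, 7),
                               rBody = 10^runif(1, 3, 5),
                               rLoad = 10^runif(1, 6, 9),
                               cLoad = runif(1, 0, 1e-8))
    mG <- GaInElectrodeModel(rIp = 10^runif(1, 4, 7),
                             cIp = runif(1, 0, 1e-8),
                             rSeries = 10^runif(1, 3, 6),
                             rLoad = 10^runif(1, 6, 9),
                             cLoad = runif(1, 0, 1e-8))
    f <- 10^runif(1, -1, 3)
    hN <- evalAt(needleTransfer(mN), f)
    hG <- evalAt(gainTransfer(mG), f)
    expect_lt(Mod(hN / oracleNeedle(mN, f) - 1), 1e-9)
    expect_lt(Mod(hG / oracleGaIn(mG, f) - 1), 1e-9)
  }

  # gelled chain against its own nodal oracle
  mGel <- GelledElectrodeModel()
  for (f in c(0.5, 5, 50, 500))
    expect_lt(Mod(evalAt(gelledTransfer(mGel), f) / oracleGelled(mGel, f) - 1),
              1e-9)
})

test_that("relative transfer is the reduced ratio with low-pass character", {
  # identical pathways give unity at every probed frequency
  tfN <- needleTransfer(NeedleElectrodeModel())
  H1 <- relativeTransfer(tfN, tfN)
  for (f in c(0.1, 1, 10, 100, 1000))
    expect_equal(Mod(evalAt(H1, f)), 1, tolerance = 1e-6)

  # default models: |H| non-increasing over the band, for several cIp
  f <- 10^seq(-1, 3, length.out = 100)
  for (cip in c(0.25e-9, 0.5e-9, 1e-9, 2e-9, 4e-9)) {
    H <- relativeTransfer(gainTransfer(GaInElectrodeModel(cIp = cip)),
                          needleTransfer(NeedleElectrodeModel()))
    mag <- bode(H, f)$magnitude_db
    expect_true(all(diff(mag) <= 1e-9))
  }

  # H agrees with the ratio of the two nodal oracles
  H <- relativeTransfer(gainTransfer(GaInElectrodeModel()),
                        needleTransfer(NeedleElectrodeModel()))
  for (f1 in c(1, 30, 300))
    expect_lt(Mod(evalAt(H, f1) /
                    (oracleGaIn(GaInElectrodeModel(), f1) /
                       oracleNeedle(NeedleElectrodeModel(), f1)) - 1), 1e-8)

  # single-pole H: -3.01 dB at the corner frequency
  tau <- 0.005
  lp <- TransferFunction(1, c(tau, 1))
  mag <- bode(lp, 1 / (2 * pi * tau))$magnitude_db
  expect_lt(abs(mag + 3.0103), 0.05)
})

test_that("bode obeys closed forms and the cascade property", {
  unity <- TransferFunction(1, 1)
  f <- c(0.1, 1, 10, 100)
  b <- bode(unity, f)
  expect_equal(b$magnitude_db, rep(0, 4))
  expect_equal(b$phase_deg, rep(0, 4))
  expect_identical(nrow(b), length(f))

  # single pole at fc: phase -45 degrees at fc
  fc <- 20
  lp <- TransferFunction(1, c(1 / (2 * pi * fc), 1))
  expect_lt(abs(bode(lp, fc)$phase_deg + 45), 0.1)

  # cascade: dB magnitudes and phases add (frequencies kept below the
  # region where the summed phase would wrap)
  lp2 <- TransferFunction(1, c(1 / (2 * pi * 50), 1))
  prod <- lp * lp2
  bp <- bode(prod, f)
  b1 <- bode(lp, f)
  b2 <- bode(lp2, f)
  expect_equal(bp$magnitude_db, b1$magnitude_db + b2$magnitude_db,
               tolerance = 1e-6)
  expect_equal(bp$phase_deg, b1$phase_deg + b2$phase_deg, tolerance = 1e-6)

  expect_error(bode(unity, numeric(0)), "empty|must not")
  expect_error(bode(unity, c(1, -2)), "positive")
})

test_that("time-domain simulation matches closed-form responses", {
  fs <- 2604
  n <- fs  # 1 s
  step <- ECGTrace(rep(1, n), fs)

  # unity transfer is the identity
  out <- simulateResponse(TransferFunction(1, 1), step)
  expect_lt(max(abs(samples(out) - samples(step))), 1e-9)
  expect_identical(traceMetadata(out)$method, "simulated")

  # single-pole step response matches 1 - exp(-t/tau) within 1% after the
  # first few samples; the trapezoidal discretisation sees the sampled step
  # as switching half a sample before the first output point
  tau <- 0.005
  y <- samples(simulateResponse(TransferFunction(1, c(tau, 1)), step))
  t <- (seq_len(n) - 1 + 0.5) / fs
  ref <- 1 - exp(-t / tau)
  sel <- 4:n
  expect_lt(max(abs(y[sel] - ref[sel]) / ref[sel]), 0.01)

  # corner above Nyquist warns but still computes
  expect_warning(simulateResponse(TransferFunction(1, c(1 / (2 * pi * 2000), 1)),
                                  step), "Nyquist")

  # degenerate division guard
  zeroTf <- TransferFunction(0, 1)
  expect_error(relativeTransfer(gainTransfer(GaInElectrodeModel()), zeroTf),
               "zero")
})

test_that("transfer-function container enforces its invariants", {
  expect_error(TransferFunction(c(1, 2, 3), c(1, 1)), "degree|denominator")
  expect_error(TransferFunction(1, 0), "denominator")
  tf <- TransferFunction(c(2, 4), c(2, 1))
  expect_identical(denominator(tf)[1], 1)  # normalised leading coefficient
  expect_equal(numerator(tf), c(1, 2))
})
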