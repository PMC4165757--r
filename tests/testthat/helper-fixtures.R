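# shared fixtures: the standard trapezoid train and a complex-impedance
# nodal oracle independent of the rational-function code path

standardShape <- function() {
  BeatShape(amplitude = 1e-3, riseTime = 0.010, plateauTime = 0.030,
            fallTime = 0.020, undershootFraction = 0)
}

cleanConfig <- function(heartRate = 2, duration = 10, seed = 1, ...) {
  syntheticConfig(heartRate = heartRate, duration = duration, seed = seed,
                  beatShape = standardShape(), ...)
}

# direct nodal arithmetic at s = j 2 pi f: an oracle for the divider
# transfer functions that never touches the package's polynomial algebra
zPar <- function(R, C, s) if (C > 0) R / (1 + s * R * C) else R + 0i * s

oracleNeedle <- function(m, f) {
  s <- 1i * 2 * pi * f
  zl <- zPar(m@rLoad, m@cLoad, s)
  zl / (zl + zPar(m@rEh, m@cEh, s) + m@rBody)
}

oracleGaIn <- function(m, f) {
  s <- 1i * 2 * pi * f
  zl <- zPar(m@rLoad, m@cLoad, s)
  zl / (zl + m@rSeries + zPar(m@rIp, m@cIp, s))
}

oracleGelled <- function(m, f) {
  s <- 1i * 2 * pi * f
  zl <- zPar(m@rLoad, m@cLoad, s)
  zl / (zl + m@rE + zPar(m@rEe, m@cEe, s) + m@rP + zPar(m@rPh, m@cPh, s))
}

evalAt <- function(tf, f) evalTransfer(tf, 1i * 2 * pi * f)
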