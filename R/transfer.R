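#' Evaluate a transfer function at complex frequencies
#'
#' @param tf a [TransferFunction-class].
#' @param s complex vector of Laplace-variable values (use \code{1i * 2 * pi
#'   * f} for steady-state response at frequency f in Hz).
#' @return Complex vector of H(s) values.
#' @export
evalTransfer <- function(tf, s) {
  stopifnot(is(tf, "TransferFunction"))
  polyEval(tf@numerator, as.complex(s)) /
    polyEval(tf@denominator, as.complex(s))
}

#' Relative transfer function between two electrode pathways
#'
#' Forms \eqn{H(s) = H_{GaIn}(s) / H_{needle}(s)}, the transfer function
#' relating the noninvasive to the invasive recording of the same cardiac
#' source, and cancels common factors (shared load/source terms) to
#' numerical tolerance. For an RC GaIn interface against a resistive needle
#' path the result is a first-order low-pass: the noninvasive waveform is a
#' slightly smoothed copy of the invasive one.
#'
#' @param gainTf transfer function of the noninvasive (GaIn) pathway.
#' @param needleTf transfer function of the invasive (needle) pathway; must
#'   not vanish at s = 0.
#' @param tol relative tolerance for root cancellation.
#' @return A [TransferFunction-class] for V_GaIn / V_needle.
#' @examples
#' H <- relativeTransfer(gainTransfer(GaInElectrodeModel()),
#'                       needleTransfer(NeedleElectrodeModel()))
#' @export
relativeTransfer <- function(gainTf, needleTf, tol = 1e-6) {
  stopifnot(is(gainTf, "TransferFunction"), is(needleTf, "TransferFunction"))
  dcNeedle <- polyEval(needleTf@numerator, 0 + 0i)
  if (Mod(dcNeedle) == 0)
    stop("needle transfer function has a zero at s = 0; relative transfer undefined")
  ## probe the band: a numerically-zero needle response cannot be divided out
  f <- c(0.1, 1, 10, 100, 1000)
  if (all(Mod(evalTransfer(needleTf, 1i * 2 * pi * f)) < 1e-300))
    stop("needle transfer function is numerically zero over the band")
  r <- ratReduce(ratDiv(list(num = gainTf@numerator, den = gainTf@denominator),
                        list(num = needleTf@numerator,
                             den = needleTf@denominator)),
                 tol = tol)
  TransferFunction(r$num, r$den)
}

#' Bode analysis of a transfer function
#'
#' Magnitude \eqn{20 \log_{10} |H(j 2 \pi f)|} and phase
#' \eqn{\arg H(j 2 \pi f)} at the requested frequencies.
#'
#' @param tf a [TransferFunction-class].
#' @param freqs positive frequencies in Hz.
#' @return A data.frame with columns \code{freq_hz}, \code{magnitude_db},
#'   \code{phase_deg}.
#' @examples
#' bode(TransferFunction(1, c(1 / (2 * pi * 30), 1)),
#'      freqs = 10^seq(0, 3, length.out = 7))
#' @export
setMethod("bode", signature("TransferFunction", "numeric"),
  function(tf, freqs) {
    if (length(freqs) == 0L) stop("frequency list must not be empty")
    if (any(!is.finite(freqs) | freqs <= 0))
      stop("all frequencies must be positive and finite")
    h <- evalTransfer(tf, 1i * 2 * pi * freqs)
    data.frame(freq_hz = freqs,
               magnitude_db = 20 * log10(Mod(h)),
               phase_deg = Arg(h) * 180 / pi)
  })

#' Discretise a transfer function at a sampling rate
#'
#' Bilinear (Tustin) transform without frequency pre-warping: the circuit
#' corners of interest sit far below the 1302 Hz Nyquist frequency of the
#' 2604 Hz recordings, where warping is negligible.
#'
#' @param tf a [TransferFunction-class] (proper).
#' @param fs sampling rate (Hz).
#' @return List with digital filter coefficients \code{b}, \code{a}.
#' @export
discretizeTransfer <- function(tf, fs) {
  stopifnot(is(tf, "TransferFunction"), fs > 0)
  ratBilinear(tf@numerator, tf@denominator, fs)
}

#' Apply a transfer function to a sampled trace
#'
#' Discretises \code{tf} at the trace's sampling rate via the bilinear
#' transform and filters the samples. Output has identical length, rate and
#' start time; metadata \code{method} is set to \code{"simulated"}.
#'
#' A warning (not an error) is raised when the transfer function has a pole
#' above the Nyquist frequency, where the discretisation is inaccurate.
#'
#' @param tf a proper [TransferFunction-class].
#' @param trace an [ECGTrace-class].
#' @return The filtered [ECGTrace-class].
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 5))
#' lp <- TransferFunction(1, c(0.005, 1))
#' sim <- simulateResponse(lp, tr)
#' @export
setMethod("simulateResponse", signature("TransferFunction", "ECGTrace"),
  function(tf, trace) {
    fs <- samplingRate(trace)
    poles <- if (length(tf@denominator) > 1L)
      polyroot(rev(tf@denominator)) else complex(0)
    if (length(poles) && any(Mod(poles) / (2 * pi) > fs / 2))
      warning("transfer-function corner above Nyquist (",
              signif(fs / 2, 5), " Hz); discretisation will be inaccurate")
    co <- ratBilinear(tf@numerator, tf@denominator, fs)
    y <- as.numeric(signal::filter(co$b, co$a, samples(trace)))
    replaceSamples(trace, y, method = "simulated")
  })

#' Write a Bode table to a delimited text file
#'
#' @param bodeTable data.frame as returned by [bode()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeBodeTable <- function(bodeTable, path) {
  stopifnot(all(c("freq_hz", "magnitude_db", "phase_deg") %in%
                names(bodeTable)))
  utils::write.table(format(bodeTable, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
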