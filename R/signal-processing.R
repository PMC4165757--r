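#' Design coefficients for the second-order IIR notch
#'
#' Constrained biquad with zeros on the unit circle at the notch frequency,
#' unity gain at DC and Nyquist, and a -3 dB rejection bandwidth of
#' \code{centerFreq / quality}. This is the classic design used for mains
#' rejection in biosignal work.
#'
#' @param centerFreq notch centre (Hz), below Nyquist.
#' @param quality quality factor Q = centre / (-3 dB bandwidth).
#' @param fs sampling rate (Hz).
#' @return List with \code{b}, \code{a} digital coefficients.
#' @export
notchDesign <- function(centerFreq, quality, fs) {
  if (centerFreq <= 0 || centerFreq >= fs / 2)
    stop("notch centre frequency must lie strictly between 0 and Nyquist (",
         fs / 2, " Hz)")
  if (quality <= 0) stop("quality factor must be > 0")
  w0 <- 2 * pi * centerFreq / fs
  bw <- w0 / quality
  gb <- 1 / sqrt(2)                      # -3 dB
  beta <- (sqrt(1 - gb^2) / gb) * tan(bw / 2)
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  list(b = b, a = a)
}

#' 60 Hz notch filter
#'
#' Second-order IIR notch, the first stage of the standard preprocessing for
#' these recordings: centre 60 Hz, quality factor 10 (-3 dB bandwidth 6 Hz)
#' at the 2604 Hz sampling rate.
#'
#' @param trace an [ECGTrace-class].
#' @param centerFreq notch centre (Hz); default 60.
#' @param quality quality factor; default 10.
#' @return Filtered [ECGTrace-class], same length and rate.
#' @seealso [preprocess()], [notchDesign()]
#' @export
notchFilter <- function(trace, centerFreq = 60, quality = 10) {
  stopifnot(is(trace, "ECGTrace"))
  co <- notchDesign(centerFreq, quality, samplingRate(trace))
  replaceSamples(trace, as.numeric(signal::filter(co$b, co$a, samples(trace))))
}

#' Centred moving-average smoothing
#'
#' Zero-phase moving average over \code{window} samples (200 by default,
#' 77 ms at 2604 Hz). Near the edges the window shrinks symmetrically so the
#' output keeps the input length. A centred (rather than causal) average is
#' used so beat timing is not skewed; these recordings are analysed offline.
#'
#' @param trace an [ECGTrace-class].
#' @param window window length in samples, between 1 and the trace length.
#' @return Smoothed [ECGTrace-class].
#' @export
movingAverage <- function(trace, window = 200) {
  stopifnot(is(trace, "ECGTrace"))
  x <- samples(trace)
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window > n)
    stop("window must be between 1 and the trace length (", n, ")")
  ## cumulative-sum moving mean; interior windows span [i - hl, i + hr],
  ## edge windows shrink symmetrically around i
  hl <- window %/% 2L
  hr <- window - 1L - hl
  i <- seq_len(n)
  lo <- i - hl
  hi <- i + hr
  edge <- lo < 1L | hi > n
  if (any(edge)) {
    m <- pmin(i - 1L, n - i, hl)
    lo[edge] <- (i - m)[edge]
    hi[edge] <- (i + m)[edge]
  }
  cs <- c(0, cumsum(x))
  replaceSamples(trace, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Standard preprocessing chain
#'
#' The notch filter followed by the moving average, with the standard
#' parameters: 60 Hz notch at quality factor 10, then a 200-point moving
#' average, removing powerline interference and broadband environmental
#' noise before beat detection.
#'
#' @param trace an [ECGTrace-class].
#' @param notchFreq,notchQ notch parameters, see [notchFilter()].
#' @param maWindow moving-average window (samples), see [movingAverage()].
#' @return Preprocessed [ECGTrace-class].
#' @examples
#' tr <- generateTrace(syntheticConfig(heartRate = 2, duration = 10,
#'                                     powerlineAmplitude = 1e-3))
#' clean <- preprocess(tr)
#' @export
preprocess <- function(trace, notchFreq = 60, notchQ = 10, maWindow = 200) {
  movingAverage(notchFilter(trace, notchFreq, notchQ), maWindow)
}
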