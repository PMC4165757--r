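---
title: "Electrode-interface models and ECG analysis for Drosophila pupae"
author: "pupaECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode-interface models and ECG analysis for Drosophila pupae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupaECG)
```

## The problem

Drosophila pupae are a convenient system for cardiac electrophysiology: the
white pupa is immobile and semi-transparent, so the heartbeat can be
recorded without dissection or anaesthesia. Two recording routes exist.
Invasive tungsten needle probes inserted through the puparium give a strong
signal but destabilise the preparation over minutes; a noninvasive surface
electrode of liquid eutectic gallium-indium (GaIn) conforms to the puparium
and preserves the animal, at the cost of recording through the
puparium's impedance. This package models both electrode-tissue
interfaces as lumped RC circuits, derives the transfer function that maps
the invasive recording onto the noninvasive one, and implements the signal
chain used to analyse such recordings: mains notch filtering,
moving-average smoothing, beat detection, period statistics at fixed
offsets, long-recording stability analysis, and waveform feature
extraction. A synthetic-data generator reproduces the statistical structure
the analysis assumes, so the whole chain is testable without any recordings.

## Equivalent circuits and the relative transfer function

Each electrode pathway is a series voltage divider from the cardiac source
into the amplifier load `rLoad // cLoad`:

* **Needle** (`NeedleElectrodeModel`): interface `cEh // rEh` in series
  with the hemocoel bulk resistance `rBody`. The voltage across the load
  is `V_needle`.
* **Gelled** (`GelledElectrodeModel`): electrolyte `rE`, interface
  `cEe // rEe`, puparium `rP`, interface `cPh // rPh`. Because the puparium
  is an ion-semipermeable membrane, a DC potential `ePe` appears in series;
  it is a Nernst potential (`nernstPotential()`, computed as
  \(E = \frac{RT}{zF}\ln([C]_{out}/[C]_{in})\) with CODATA constants) and
  enters the recording as an additive offset, not as part of the transfer
  function.
* **GaIn** (`GaInElectrodeModel`): interface `rIp // cIp` plus a series DC
  resistance `rSeries`. This is the minimal topology consistent with an
  interface-impedance-plus-DC-resistance description of the GaIn contact.

Transfer functions are derived symbolically by series/parallel impedance
algebra over these chains (the package carries its own small
rational-function layer; each divider is
\(H(s) = Z_{load}/(Z_{load} + \sum Z_{series})\)). Tests pin every model
against an independent complex nodal oracle at random frequencies
(agreement to 1e-9 relative) and against the resistive-divider limit when
all capacitances vanish.

The quantity of interest is the relative transfer function

\[
H(s) = \frac{V_{GaIn}(s)}{V_{needle}(s)},
\]

formed by `relativeTransfer()` as the reduced ratio of the two pathway
transfer functions (shared factors, e.g. the common load pole, are
cancelled by root matching to a 1e-6 relative tolerance — loose enough to
absorb `polyroot()` error on near-double roots, far tighter than any
genuine corner separation). For an RC GaIn interface against a resistive
needle path, H is a low-pass: the noninvasive waveform is a slightly
smoothed, slightly attenuated image of the invasive one.

```{r transfer}
H <- relativeTransfer(gainTransfer(GaInElectrodeModel()),
                      needleTransfer(NeedleElectrodeModel()))
bode(H, c(1, 10, 30, 100, 300, 1000))
```

No component values are published for these interfaces, so the constructor
defaults are *illustrative*: they are chosen to place the corner of H near
30 Hz — inside the cardiac signal band, so the low-pass effect is visible
in demonstrations — and to keep every pole of H below the 1302 Hz Nyquist
frequency of the standard recordings, where the bilinear discretisation
used by `simulateResponse()` is accurate. The bilinear transform is applied
without frequency pre-warping because all corners sit far below Nyquist;
the step-response tests budget the residual discretisation error at under
1% from the fourth sample on.

## The synthetic recordings

`generateTrace()` emulates what the analysis chain assumes about a pupal
ECG recording:

* a pulse train of trapezoidal beats (`BeatShape`: linear rise, plateau,
  linear fall, optional undershoot). The trapezoid is deliberate: no
  analytic description of pupal beat morphology exists, and a
  piecewise-linear beat makes positive duration and both edge slopes
  analytically known for testing. The standard shape is 1 mV, 10/30/20 ms
  rise/plateau/fall.
* per-beat period jitter, i.i.d. normal (default sd 10 ms in the presets),
  truncated so consecutive beats never overlap;
* additive contamination: mains sinusoid (60 Hz), white noise, slow
  baseline wander;
* slow drifts that distinguish recording methods: beat amplitude follows
  \((1-r)^{t/60}\) (fraction r lost per minute) and the beat period grows
  linearly in time. The `phenotypePreset(..., method = "invasive")` preset
  uses r = 3%/min and 2%/min period lengthening; `"noninvasive"` is
  stationary. These encode the observed contrast in 15-minute recordings:
  the needle preparation degrades, the GaIn one does not.
* an optional AC-coupled amplifier stage (first-order band-pass 5 Hz-10 kHz
  plus gain, off by default) mirroring the bench front-end.

Phenotype presets order the heart rates as wild-type Canton-S (CS) fastest,
the NP1029-GAL4 driver control (NP) intermediate, and SERCA-depleted
slowest. The numeric values (4, 3, 1.5 Hz) are implementer choices that
honour only that ordering — no numeric rates are published — and every
preset magnitude is configurable. The generator records its ground truth
(beat onsets, peak times, per-beat amplitudes) in the trace metadata, so
detector and estimator tests score against construction rather than against
another estimator. Identical configurations give bitwise-identical traces.

What the generator does **not** emulate: real pupal ECG morphology (no
published analytic shape exists), non-stationary noise, electrode motion
artifacts beyond smooth drift, or any biophysical cardiomyocyte dynamics.
Passing tests therefore demonstrate that the analysis chain measures what
it claims on signals with known structure — not that the chain is validated
on real recordings.

## The signal chain

`preprocess()` is the standard two-stage chain for these recordings: a
second-order IIR notch at 60 Hz with quality factor 10, then a 200-point
moving average (77 ms at the 2604 Hz protocol sampling rate). The notch is
the constrained biquad with zeros on the unit circle at the notch
frequency; unity gain at DC and Nyquist and a -3 dB rejection bandwidth of
centre/Q are exact by construction, and the tests measure the realised Q at
10.02. The moving average is *centred* (zero phase) with symmetric shrink
at the edges: recordings are analysed offline, and a centred window avoids
skewing beat times the way a causal one would.

`detectBeats()` is wholly artifact-designed (no beat detector is published
for these data): upward crossings of
`baseline + 0.5 * (robust peak - baseline)`, with the baseline at the trace
median, the robust peak at the 99th percentile, a 100 ms refractory
lockout, and refinement to the local maximum of the supra-threshold run.
The 99th percentile (rather than a lower quantile) matters at slow rates:
at 0.5 Hz a 60 ms beat occupies ~3% of samples, so a 95th-percentile
"peak" would sit on the baseline. Beat times snap to the sample grid; at
2604 Hz the 0.38 ms quantisation is negligible against period scales.
`periodSummary()` implements the offset protocol — the first ≥20 periods
starting 10, 100 and 1000 s into the recording, with a validity flag and
the achieved count when data run short.

`stabilityAnalysis()` cuts a long recording into non-overlapping windows
(60 s default), collects mean beat peak amplitude (peak amplitude was
chosen over RMS as the more interpretable per-beat measure) and mean
period per window, and
reports the least-squares amplitude slope as a fraction of the first valid
window per minute, plus the coefficient of variation of all periods.
Windows with fewer than two beats are flagged and excluded. Note one
deliberate bias left in place: the least-squares slope of an exponential
decay underestimates the per-minute rate slightly (about 11% at 3%/min
over 15 minutes); the tests budget 20% for recovery rather than linearise
the truth, because the linear trend is the reported statistic.

## Waveform features and the interface fit

`extractFeatures()` measures, per beat and averaged across beats: positive
duration (time above the median baseline around the peak, with a 1e-6
relative tolerance above baseline so exponentially decaying filter tails
terminate), the depolarization slope (least-squares fit over the 10-90%
amplitude segment of the rising edge), and the repolarization slope
(likewise, falling edge; "polarization slope" in the field's usage). The
10-90% convention is robust to smoothing, unlike a peak derivative. On the
standard trapezoid these are analytically 60 ms, +0.1 V/s and -0.05 V/s,
which the tests verify to within two samples / 5%.

`fitRelativeTransfer()` estimates a first-order interface model
\(H(s) = g/(\tau s + 1)\) from a paired invasive/noninvasive recording by
minimising the RMS difference between the filtered invasive trace and the
observed noninvasive one. The fit is restricted to first order because the
interface difference is attributed to a single `rIp // cIp` element. The
optimiser is a deterministic coarse grid (gains around the amplitude ratio,
a log-spaced tau grid including 0) followed by Nelder-Mead refinement that
is never allowed to return a worse point than the grid; there are no random
starts, so results are reproducible. Noise-free recovery across a 3x3
generating grid is exact to well under 1%, and at 40 dB SNR both
parameters return within 10%.

## Numerical and design notes

* Problem sizes in the shipped tests and acceptance script: 8-30 s traces
  for calibration and fitting, two 15-minute traces for the stability
  contrast, 20 random models for oracle agreement, a 0.01 Hz grid for the
  notch characterisation. These are the sizes at which every quantity of
  interest is stable to well inside its test tolerance.
* All filtering applies coefficients via `signal::filter`; coefficient
  *design* (notch biquad, bilinear substitution) is implemented in the
  package, as is the rational-function algebra behind the circuit models.
* Degenerate inputs: zero-amplitude beats give an all-zero template; traces
  with no threshold crossings give an empty `BeatSeries` (not an error); a
  needle transfer with a zero at s = 0 makes the relative transfer
  undefined and errors; a transfer-function corner above Nyquist warns but
  proceeds.
* File formats are plain delimited text with `#`-prefixed key/value
  headers; voltage units V, mV, uV/µV and nV are honoured on read, traces
  are always written in volts, and every pipeline artifact embeds the
  parameters that produced it. Time grids must be uniform to 1 ns and
  consistent with the stated sampling rate.

## Limitations

The electrode component values are illustrative, not measured; the gelled
pathway is modelled but no gelled-vs-needle comparison is implemented
(the noninvasive route of interest is GaIn); no arrhythmia classification,
HRV spectral analysis, multi-channel support, or hypothesis testing between
phenotypes is provided; and the synthetic generator's fidelity bounds what
the test suite can claim about real recordings.
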