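#' Constructors for the electrode equivalent-circuit models
#'
#' Default component values are illustrative (no component values are
#' published for these interfaces); the GaIn defaults place the corner of
#' the relative transfer function near 30 Hz, inside the cardiac signal
#' band, so its low-pass effect on waveforms is visible in demonstrations.
#'
#' @param cEh,rEh needle-hemocoel interface capacitance (F) and resistance
#'   (ohm).
#' @param rBody hemocoel bulk resistance (ohm).
#' @param rE electrolyte resistance (ohm).
#' @param rP puparium resistance (ohm).
#' @param cEe,rEe electrode-electrolyte interface (F, ohm).
#' @param cPh,rPh puparium-hemocoel interface (F, ohm).
#' @param ePe DC interface potential across the puparium (V); see
#'   [nernstPotential()].
#' @param rIp,cIp GaIn-puparium interface resistance (ohm) and capacitance
#'   (F).
#' @param rSeries series DC resistance of the GaIn path (ohm).
#' @param rLoad,cLoad amplifier input load (ohm, F).
#' @return The corresponding electrode model object.
#' @seealso [ElectrodeModels] for the circuit topologies,
#'   [needleTransfer()], [gainTransfer()], [gelledTransfer()].
#' @examples
#' H <- relativeTransfer(gainTransfer(GaInElectrodeModel()),
#'                       needleTransfer(NeedleElectrodeModel()))
#' bode(H, c(1, 10, 30, 100, 300))
#' @name electrodeModelConstructors
NULL

#' @rdname electrodeModelConstructors
#' @export
NeedleElectrodeModel <- function(cEh = 0, rEh = 1e4, rBody = 4e4,
                                 rLoad = 100e6, cLoad = 2.4e-9) {
  new("NeedleElectrodeModel", cEh = cEh, rEh = rEh, rBody = rBody,
      rLoad = rLoad, cLoad = cLoad)
}

#' @rdname electrodeModelConstructors
#' @export
GelledElectrodeModel <- function(rE = 10e3, rP = 2e6, cEe = 100e-9, rEe = 1e6,
                                 cPh = 50e-9, rPh = 5e6, ePe = 0.02,
                                 rLoad = 100e6, cLoad = 2.4e-9) {
  new("GelledElectrodeModel", rE = rE, rP = rP, cEe = cEe, rEe = rEe,
      cPh = cPh, rPh = rPh, ePe = ePe, rLoad = rLoad, cLoad = cLoad)
}

#' @rdname electrodeModelConstructors
#' @export
GaInElectrodeModel <- function(rIp = 1.25e6, cIp = 1e-9, rSeries = 1e6,
                               rLoad = 100e6, cLoad = 2.4e-9) {
  new("GaInElectrodeModel", rIp = rIp, cIp = cIp, rSeries = rSeries,
      rLoad = rLoad, cLoad = cLoad)
}

#' Nernst potential across an ion-semipermeable membrane
#'
#' The equilibrium potential set by a transmembrane concentration ratio:
#' \deqn{E = \frac{RT}{zF} \ln\frac{[C]_{out}}{[C]_{in}}}
#' with the molar gas constant R = 8.314462618 J/(mol K) and the Faraday
#' constant F = 96485.33212 C/mol (CODATA). In the gelled-electrode circuit
#' this supplies the DC interface potential across the puparium
#' (\code{ePe} in [GelledElectrodeModel()]).
#'
#' @param temperature absolute temperature (K), > 0.
#' @param valence signed ionic charge number, nonzero integer.
#' @param concOutside,concInside ion concentrations (mol/L), > 0. Only their
#'   ratio matters.
#' @return Potential in volts.
#' @examples
#' nernstPotential(298.15, 1, 10, 1)  # ~ +59.2 mV per decade at 25 C
#' @export
nernstPotential <- function(temperature, valence, concOutside, concInside) {
  R <- 8.314462618    # J / (mol K)
  Faraday <- 96485.33212  # C / mol
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 K")
  if (valence == 0 || valence != round(valence))
    stop("valence must be a nonzero integer")
  if (!is.finite(concOutside) || concOutside <= 0 ||
      !is.finite(concInside) || concInside <= 0)
    stop("concentrations must be > 0")
  (R * temperature) / (valence * Faraday) * log(concOutside / concInside)
}

## voltage divider from a series chain of impedances into the load:
## H(s) = Zload / (Zload + sum(chain))
dividerTransfer <- function(chain, rLoad, cLoad) {
  zLoad <- impParallelRC(rLoad, cLoad)
  zTot <- zLoad
  for (z in chain) zTot <- ratAdd(zTot, z)
  r <- ratDiv(zLoad, zTot)
  TransferFunction(r$num, r$den)
}

#' @rdname electrodeTransfer
#' @details
#' \code{needleTransfer}: the invasive chain is the needle-hemocoel
#' interface (cEh // rEh) in series with the hemocoel bulk rBody, loaded by
#' rLoad // cLoad; the output voltage across the load is V_needle.
#' @export
setMethod("needleTransfer", "NeedleElectrodeModel", function(model) {
  validObject(model)
  dividerTransfer(list(impParallelRC(model@rEh, model@cEh),
                       impResistor(model@rBody)),
                  model@rLoad, model@cLoad)
})

#' @rdname electrodeTransfer
#' @details
#' \code{gainTransfer}: the noninvasive (GaIn) chain is the series DC
#' resistance rSeries plus the interface impedance rIp // cIp; the output
#' across the load is V_GaIn.
#' @export
setMethod("gainTransfer", "GaInElectrodeModel", function(model) {
  validObject(model)
  dividerTransfer(list(impResistor(model@rSeries),
                       impParallelRC(model@rIp, model@cIp)),
                  model@rLoad, model@cLoad)
})

#' @rdname electrodeTransfer
#' @details
#' \code{gelledTransfer}: electrolyte rE, electrode-electrolyte interface
#' cEe // rEe, puparium rP, puparium-hemocoel interface cPh // rPh, into the
#' load. The DC interface potential ePe is a series source and therefore an
#' additive offset on the recorded signal, not part of the transfer
#' function; it is left to the caller (e.g. added to simulated outputs).
#' @export
setMethod("gelledTransfer", "GelledElectrodeModel", function(model) {
  validObject(model)
  dividerTransfer(list(impResistor(model@rE),
                       impParallelRC(model@rEe, model@cEe),
                       impResistor(model@rP),
                       impParallelRC(model@rPh, model@cPh)),
                  model@rLoad, model@cLoad)
})
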