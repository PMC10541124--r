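#' Bond affinity from binding and unbinding rate constants
#'
#' The free-energy gain of forming a bond, in units of \eqn{k_B T}, for a
#' dynamic bond with association rate constant \code{kon} and dissociation
#' rate constant \code{koff}: \eqn{\epsilon = \ln(k_{on}/k_{off})}.  Raising
#' the affinity therefore corresponds to lowering \code{koff} at fixed
#' \code{kon}.
#'
#' @param kon association rate constant (1/time; any unit, shared with koff)
#' @param koff dissociation rate constant (same unit as \code{kon})
#' @return affinity in \eqn{k_B T}
#' @examples
#' bondAffinity(50, 0.001)   # ~10.8 kBT
#' bondAffinity(50, 0.0001)  # ~13.1 kBT
#' @export
bondAffinity <- function(kon, koff) {
  if (any(kon <= 0) || any(koff <= 0))
    stop("bondAffinity: rate constants must be positive")
  log(kon / koff)
}

#' Molar concentration of a molecule count in a simulation box
#'
#' @param count number of molecules
#' @param box a \linkS4class{SimulationBox} (edges in nm)
#' @return concentration in micromolar
#' @examples
#' molarConcentration(1170, SimulationBox(860))  # ~3 uM
#' @export
molarConcentration <- function(count, box) {
  if (any(count < 0)) stop("molarConcentration: count must be non-negative")
  v_l <- boxVolume(box) * 1e-24  # nm^3 -> litres
  if (v_l <= 0) stop("molarConcentration: box volume must be positive")
  count / (.NAvogadro * v_l) * 1e6
}

#' Count ratio of two species that balances their complementary sites
#'
#' For species A with \code{valenceA} sites and species B with
#' \code{valenceB} complementary sites, the count ratio A:B that equalises
#' the total number of sites on each side is \code{valenceB / valenceA};
#' e.g. a divalent rod and a hexavalent hub balance at 3:1.
#'
#' @param valenceA,valenceB site counts per molecule, both positive
#' @return the count ratio of A to B
#' @export
stoichiometricRatio <- function(valenceA, valenceB) {
  if (valenceA <= 0 || valenceB <= 0)
    stop("stoichiometricRatio: valences must be positive")
  valenceB / valenceA
}

#' Calibrate the simulation time unit against a physical diffusivity
#'
#' Matches a diffusivity measured in simulation units (\eqn{\mu m^2/\tau},
#' typically the fitted MSD slope of the 40-nm inert tracer species) to a
#' target physical value (\eqn{\mu m^2/s}), giving the duration of one
#' simulation time unit in seconds: \eqn{\tau = D_{sim}/D_{target}}.
#'
#' @param dSim diffusivity in simulation units (\eqn{\mu m^2/\tau})
#' @param dTarget physical diffusivity (\eqn{\mu m^2/s})
#' @return seconds per simulation time unit
#' @export
calibrateTimeUnit <- function(dSim, dTarget) {
  if (dSim <= 0 || dTarget <= 0)
    stop("calibrateTimeUnit: diffusivities must be positive")
  dSim / dTarget
}
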