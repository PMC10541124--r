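# S4 containers for species geometry, system composition and simulation state.

#' Rigid-body geometry and binding-patch layout of one molecular species
#'
#' A species is a rigid assembly of one or more spheres (the excluded-volume
#' body) decorated with zero or more binding sites ("patches").  Site
#' directions are unit vectors in the body frame; the stored site offsets are
#' the actual body-frame centres of the site spheres.  Species with no sites
#' (crowders, tracers) have zero valence.
#'
#' @slot name species label
#' @slot bodyDiameters diameters (nm) of the constituent spheres
#' @slot bodyOffsets 3 x n matrix of sphere centres in the body frame (nm)
#' @slot siteUnitVectors 3 x v matrix of unit patch directions (body frame)
#' @slot siteOffsets 3 x v matrix of patch-sphere centres (body frame, nm)
#' @slot siteDiameter diameter of the patch spheres (nm)
#' @slot siteType patch class: "none", or one of the complementary classes
#'   "A" (hexamer-type) and "B" (dimer-type)
#' @slot temperatureGroup thermostat group label (crowders get their own)
#' @slot effectiveDiameter single diameter (nm) used by the drag rule
#' @export
setClass("SpeciesSpec", representation(
  name = "character", bodyDiameters = "numeric", bodyOffsets = "matrix",
  siteUnitVectors = "matrix", siteOffsets = "matrix", siteDiameter = "numeric",
  siteType = "character", temperatureGroup = "character",
  effectiveDiameter = "numeric"))

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (any(object@bodyDiameters <= 0)) msg <- c(msg, "body diameters must be > 0")
  if (ncol(object@bodyOffsets) != length(object@bodyDiameters))
    msg <- c(msg, "one body offset per body sphere required")
  v <- ncol(object@siteUnitVectors)
  if (ncol(object@siteOffsets) != v)
    msg <- c(msg, "siteOffsets and siteUnitVectors must agree in valence")
  if (v > 0) {
    nn <- sqrt(colSums(object@siteUnitVectors^2))
    if (any(abs(nn - 1) > 1e-6)) msg <- c(msg, "site vectors must have unit norm")
    if (object@siteType == "none")
      msg <- c(msg, "species with sites needs a patch class")
  }
  if (object@siteDiameter < 0) msg <- c(msg, "site diameter must be >= 0")
  if (!object@siteType %in% c("none", "A", "B"))
    msg <- c(msg, "siteType must be 'none', 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpeciesSpec number of binding patches
#' @param object,x a \code{SpeciesSpec}
#' @export
valence <- function(x) ncol(x@siteUnitVectors)

#' @export
setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf("SpeciesSpec '%s': %d sphere(s), valence %d (%s), drag diameter %.2f nm\n",
              object@name, length(object@bodyDiameters),
              valence(object), object@siteType, object@effectiveDiameter))
})

#' Simulation box
#'
#' @slot edgeLengths the three edge lengths in nm
#' @slot boundaryMode "periodic" or "walled" (closed box with repulsive walls)
#' @export
setClass("SimulationBox", representation(
  edgeLengths = "numeric", boundaryMode = "character"))

setValidity("SimulationBox", function(object) {
  msg <- character()
  if (length(object@edgeLengths) != 3 || any(object@edgeLengths <= 0))
    msg <- c(msg, "three positive edge lengths required")
  if (!object@boundaryMode %in% c("periodic", "walled"))
    msg <- c(msg, "boundaryMode must be 'periodic' or 'walled'")
  if (length(msg)) msg else TRUE
})

#' @param edge one edge (cubic box) or three edge lengths, nm
#' @param boundaryMode "periodic" or "walled"
#' @rdname SimulationBox-class
#' @export
SimulationBox <- function(edge, boundaryMode = "periodic") {
  if (length(edge) == 1) edge <- rep(edge, 3)
  new("SimulationBox", edgeLengths = as.numeric(edge), boundaryMode = boundaryMode)
}

#' @describeIn SimulationBox-class box volume in nm^3
#' @param box a \code{SimulationBox}
#' @export
boxVolume <- function(box) prod(box@edgeLengths)

#' @export
setMethod("show", "SimulationBox", function(object) {
  cat(sprintf("SimulationBox %.4g x %.4g x %.4g nm (%s)\n",
              object@edgeLengths[1], object@edgeLengths[2],
              object@edgeLengths[3], object@boundaryMode))
})

#' System composition: species roster, copy numbers and box
#'
#' @slot species named list of \linkS4class{SpeciesSpec}
#' @slot counts named integer vector, same names as \code{species}
#' @slot box a \linkS4class{SimulationBox}
#' @export
setClass("SystemComposition", representation(
  species = "list", counts = "numeric", box = "SimulationBox"))

setValidity("SystemComposition", function(object) {
  msg <- character()
  if (!identical(names(object@species), names(object@counts)))
    msg <- c(msg, "species and counts must share names")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be whole numbers")
  if (length(msg)) msg else TRUE
})

#' @param species named list of \code{SpeciesSpec}
#' @param counts named numeric vector of copy numbers
#' @param box a \code{SimulationBox}
#' @rdname SystemComposition-class
#' @export
SystemComposition <- function(species, counts, box) {
  if (is.null(names(species))) names(species) <- vapply(species, function(s) s@name, "")
  counts <- counts[names(species)]
  new("SystemComposition", species = species, counts = counts, box = box)
}

#' @export
setMethod("show", "SystemComposition", function(object) {
  cat("SystemComposition:\n")
  for (nm in names(object@species))
    cat(sprintf("  %-10s n = %6d  (%.3g uM)\n", nm, as.integer(object@counts[nm]),
                molarConcentration(object@counts[nm], object@box)))
  show(object@box)
})

#' Instantaneous configuration of all particles
#'
#' Positions are particle (body) centres in nm, centred on the box origin;
#' orientations are unit quaternions (w, x, y, z), the identity for
#' isotropic spheres.  Bonds reference molecules and site indices.
#'
#' @slot composition the \linkS4class{SystemComposition}
#' @slot speciesIndex integer species index per particle
#' @slot positions N x 3 matrix, nm
#' @slot quaternions N x 4 matrix of unit quaternions
#' @slot bonds B x 4 integer matrix: molecule_a, site_a, molecule_b, site_b
#' @slot time simulation time at this state
#' @export
setClass("SystemState", representation(
  composition = "SystemComposition", speciesIndex = "integer",
  positions = "matrix", quaternions = "matrix", bonds = "matrix",
  time = "numeric"))

setValidity("SystemState", function(object) {
  msg <- character()
  n <- nrow(object@positions)
  if (length(object@speciesIndex) != n) msg <- c(msg, "speciesIndex length mismatch")
  if (!all(is.finite(object@positions))) msg <- c(msg, "positions must be finite")
  if (nrow(object@quaternions) != n || ncol(object@quaternions) != 4)
    msg <- c(msg, "quaternions must be N x 4")
  else {
    qn <- sqrt(rowSums(object@quaternions^2))
    if (n > 0 && any(abs(qn - 1) > 1e-8)) msg <- c(msg, "quaternions must be unit norm")
  }
  if (ncol(object@bonds) != 4) msg <- c(msg, "bonds must have 4 columns")
  box <- object@composition@box
  if (n > 0 && box@boundaryMode == "periodic") {
    half <- box@edgeLengths / 2
    if (any(abs(sweep(object@positions, 2, half, "/")) > 1 + 1e-9))
      msg <- c(msg, "periodic positions must be wrapped into the box")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SystemState number of particles
#' @param state a \code{SystemState}
#' @export
nParticles <- function(state) nrow(state@positions)

#' @describeIn SystemState particle positions (N x 3, nm)
#' @export
positions <- function(state) state@positions

#' @describeIn SystemState bond table as a data.frame
#' @export
bonds <- function(state) {
  b <- state@bonds
  data.frame(molecule_a = b[, 1], site_a = b[, 2],
             molecule_b = b[, 3], site_b = b[, 4])
}

#' @describeIn SystemState species name per particle
#' @export
particleSpecies <- function(state)
  names(state@composition@species)[state@speciesIndex]

#' @export
setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d particles, %d bonds, t = %.4g\n",
              nParticles(object), nrow(object@bonds), object@time))
})

#' Recorded trajectory of a simulation run
#'
#' @slot framePositions list of N x 3 matrices
#' @slot frameBonds list of B x 4 bond matrices
#' @slot frameTimes times of the stored frames
#' @slot bondCountTimes,bondCounts bond count observed at every updater call
#' @slot finalState the \linkS4class{SystemState} at the end of the run
#' @slot events bond event log (step, event 1=form/0=break, ids), if enabled
#' @slot dt integration time step used
#' @export
setClass("SimTrajectory", representation(
  framePositions = "list", frameBonds = "list", frameTimes = "numeric",
  bondCountTimes = "numeric", bondCounts = "numeric", finalState = "SystemState",
  events = "matrix", dt = "numeric"))

#' @describeIn SimTrajectory number of stored frames
#' @param traj,object a \code{SimTrajectory}
#' @export
nFrames <- function(traj) length(traj@framePositions)

#' @export
setMethod("show", "SimTrajectory", function(object) {
  cat(sprintf("SimTrajectory: %d frames over t = [%.4g, %.4g], dt = %.3g\n",
              nFrames(object), min(object@frameTimes), max(object@frameTimes),
              object@dt))
})

#' Lag-indexed ensemble statistic over particle tracks
#'
#' Holds MSD, angle-correlation or velocity-autocorrelation curves: one value
#' per lag with the number of samples that entered each average and its
#' standard error.
#'
#' @slot lags lag values (in frames or time units, see \code{lagUnit})
#' @slot values the statistic per lag
#' @slot counts number of averaged samples per lag
#' @slot se standard error per lag
#' @slot statistic label ("msd", "angle_correlation", "vacf")
#' @slot lagUnit unit of the lag axis
#' @export
setClass("CorrelationCurve", representation(
  lags = "numeric", values = "numeric", counts = "numeric", se = "numeric",
  statistic = "character", lagUnit = "character"))

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  k <- length(object@lags)
  if (length(object@values) != k || length(object@counts) != k)
    msg <- c(msg, "lags, values, counts must have equal length")
  if (object@statistic == "angle_correlation" &&
      any(object@values < -1 - 1e-9 | object@values > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "angle correlation must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve (%s): %d lags [%s]\n", object@statistic,
              length(object@lags), object@lagUnit))
})

#' @describeIn CorrelationCurve curve as a data.frame
#' @param x a \code{CorrelationCurve}
#' @export
curveData <- function(x)
  data.frame(lag = x@lags, value = x@values, n = x@counts, se = x@se)
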