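# Parameter containers for the force field, integrator and bond updater.

#' Non-bonded force-field parameters
#'
#' The soft quartic repulsion \eqn{U(r) = \epsilon_{soft}(1 - (r/r_{cut})^4)}
#' for \eqn{r < r_{cut}} (0 beyond), with the XPLOR smoothing window starting
#' at \eqn{r_{on} = 0.95 r_{cut}}; \eqn{r_{cut}} is the sum of the radii of
#' the interacting spheres.  An optional Lennard-Jones patch attraction is
#' carried but defaults to zero strength.
#'
#' @slot epsSoft repulsion strength at full overlap, kBT (default 500)
#' @slot rOnFrac smoothing onset as a fraction of r_cut (default 0.95)
#' @slot ljEpsilon Lennard-Jones well depth between complementary patches, kBT
#' @slot ljCutoffFactor LJ cutoff as multiple of sigma (default 2.5)
#' @export
setClass("ForceFieldParams", representation(
  epsSoft = "numeric", rOnFrac = "numeric", ljEpsilon = "numeric",
  ljCutoffFactor = "numeric"))

setValidity("ForceFieldParams", function(object) {
  msg <- character()
  if (object@epsSoft < 0) msg <- c(msg, "epsSoft must be >= 0")
  if (object@rOnFrac <= 0 || object@rOnFrac > 1)
    msg <- c(msg, "rOnFrac must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param epsSoft,rOnFrac,ljEpsilon,ljCutoffFactor see slots
#' @rdname ForceFieldParams-class
#' @export
ForceFieldParams <- function(epsSoft = 500, rOnFrac = 0.95, ljEpsilon = 0,
                             ljCutoffFactor = 2.5) {
  new("ForceFieldParams", epsSoft = epsSoft, rOnFrac = rOnFrac,
      ljEpsilon = ljEpsilon, ljCutoffFactor = ljCutoffFactor)
}

#' Integrator parameters for overdamped Langevin propagation
#'
#' Two drag rules are provided.  \code{"diameter"} works in reduced units
#' (lengths nm, energies kBT, times tau): the translational diffusivity is
#' \code{referenceDiameter / d} so the reference species has D = 1 nm^2/tau,
#' and rotational diffusivity follows the sphere relation D_r = 3 D_t / d^2.
#' \code{"stokes"} works in physical units (times in seconds) with
#' D_t = kBT / (3 pi eta d) and D_r = kBT / (pi eta d^3) at the supplied
#' viscosity.  Per-group temperature factors scale only the thermal noise,
#' which is how crowders are driven at an effective temperature.
#'
#' @slot dt time step (tau, or seconds under the stokes rule)
#' @slot temperatures named temperature factors per temperature group,
#'   relative to room temperature ("default" applies to unlisted groups)
#' @slot dragRule "diameter" or "stokes"
#' @slot viscosity Pa s, used by the stokes rule
#' @slot referenceDiameter nm, used by the diameter rule
#' @slot seed integer RNG seed
#' @slot maxStepFrac instability guard: max per-step displacement as a
#'   fraction of the smallest sphere diameter
#' @export
setClass("IntegratorParams", representation(
  dt = "numeric", temperatures = "numeric", dragRule = "character",
  viscosity = "numeric", referenceDiameter = "numeric", seed = "numeric",
  maxStepFrac = "numeric"))

setValidity("IntegratorParams", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (any(object@temperatures < 0)) msg <- c(msg, "temperatures must be >= 0")
  if (!object@dragRule %in% c("diameter", "stokes"))
    msg <- c(msg, "dragRule must be 'diameter' or 'stokes'")
  if (length(msg)) msg else TRUE
})

#' @param dt,temperatures,dragRule,viscosity,referenceDiameter,seed,maxStepFrac
#'   see slots
#' @rdname IntegratorParams-class
#' @export
IntegratorParams <- function(dt = 0.002, temperatures = c(default = 1),
                             dragRule = "diameter", viscosity = 0.03,
                             referenceDiameter = 12.6, seed = 1,
                             maxStepFrac = 0.25) {
  if (is.null(names(temperatures))) names(temperatures) <- "default"
  new("IntegratorParams", dt = dt, temperatures = temperatures,
      dragRule = dragRule, viscosity = viscosity,
      referenceDiameter = referenceDiameter, seed = seed,
      maxStepFrac = maxStepFrac)
}

#' Dynamic-bonding parameters
#'
#' Under the rate-based scheme the per-updater-call probabilities are
#' \eqn{P = 1 - \exp(-k \, n \, dt)} for both binding and unbinding
#' (see \code{\link{perInvocationProbability}}) and formation is accepted
#' with the Metropolis factor for the spring energy created, so the
#' stationary ensemble is Boltzmann-consistent.  With \code{javaMode = TRUE}
#' binding is diffusion-limited (probability 1 on contact), unbinding is
#' strain-independent at rate \code{koff}, and a broken pair may not rebind
#' until it has escaped beyond the binding range.
#'
#' @slot kon association rate constant (1/time; ignored in java mode)
#' @slot koff dissociation rate constant (1/time)
#' @slot dBind critical site-site distance for a binding attempt, nm
#' @slot bindCriterion "center" (site-centre distance <= dBind) or "surface"
#'   (gap between site spheres <= dBind)
#' @slot updaterPeriod bond updater invoked every this many steps
#' @slot bondSpringK harmonic bond spring constant, kBT/nm^2
#' @slot bondRestLength spring rest length, nm
#' @slot javaMode logical, see above
#' @slot frustration logical; forbid a second bond between the same two
#'   molecules (the steric in-trans rule of the rod geometry, made explicit)
#' @export
setClass("BondingParams", representation(
  kon = "numeric", koff = "numeric", dBind = "numeric",
  bindCriterion = "character", updaterPeriod = "numeric",
  bondSpringK = "numeric", bondRestLength = "numeric", javaMode = "logical",
  frustration = "logical"))

setValidity("BondingParams", function(object) {
  msg <- character()
  if (object@kon < 0 || object@koff < 0) msg <- c(msg, "rates must be >= 0")
  if (object@dBind <= 0) msg <- c(msg, "dBind must be > 0")
  if (object@updaterPeriod < 1) msg <- c(msg, "updaterPeriod must be >= 1")
  if (!object@bindCriterion %in% c("center", "surface"))
    msg <- c(msg, "bindCriterion must be 'center' or 'surface'")
  if (length(msg)) msg else TRUE
})

#' @param kon,koff,dBind,bindCriterion,updaterPeriod,bondSpringK,
#'   bondRestLength,javaMode,frustration see slots
#' @rdname BondingParams-class
#' @export
BondingParams <- function(kon = 50, koff = 0.001, dBind = 1.0,
                          bindCriterion = "center", updaterPeriod = 10,
                          bondSpringK = 100, bondRestLength = 1.0,
                          javaMode = FALSE, frustration = TRUE) {
  new("BondingParams", kon = kon, koff = koff, dBind = dBind,
      bindCriterion = bindCriterion, updaterPeriod = updaterPeriod,
      bondSpringK = bondSpringK, bondRestLength = bondRestLength,
      javaMode = javaMode, frustration = frustration)
}

#' Return bonding parameters with binding switched off
#'
#' Used to measure the dissociation rate: let the system equilibrate, switch
#' the binding rate to zero, then fit the exponential decay of the bond
#' count.  Idempotent; only \code{kon} changes.
#'
#' @param params a \linkS4class{BondingParams}
#' @return the same parameters with \code{kon = 0}
#' @export
switchOffBinding <- function(params) {
  params@kon <- 0
  params
}

#' Linear box-compression schedule
#'
#' @slot initialEdge starting cubic edge, nm
#' @slot targetEdge final cubic edge, nm
#' @slot nSteps number of steps over which the edge is interpolated linearly
#' @export
setClass("CompressionSchedule", representation(
  initialEdge = "numeric", targetEdge = "numeric", nSteps = "numeric"))

setValidity("CompressionSchedule", function(object) {
  msg <- character()
  if (object@initialEdge < object@targetEdge)
    msg <- c(msg, "initial edge must be >= target edge")
  if (object@nSteps < 1) msg <- c(msg, "nSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param initialEdge,targetEdge,nSteps see slots
#' @rdname CompressionSchedule-class
#' @export
CompressionSchedule <- function(initialEdge = 1400, targetEdge = 860,
                                nSteps = 5e5) {
  new("CompressionSchedule", initialEdge = initialEdge,
      targetEdge = targetEdge, nSteps = nSteps)
}
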