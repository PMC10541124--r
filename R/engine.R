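# R-side driver for the compiled Brownian-dynamics kernel.

# rotate body-frame vector(s) v (3 x k) by unit quaternion q = (w,x,y,z)
.qrotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  apply(v, 2, function(x) {
    t <- 2 * c(u[2] * x[3] - u[3] * x[2],
               u[3] * x[1] - u[1] * x[3],
               u[1] * x[2] - u[2] * x[1])
    x + w * t + c(u[2] * t[3] - u[3] * t[2],
                  u[3] * t[1] - u[1] * t[3],
                  u[1] * t[2] - u[2] * t[1])
  })
}

.randomQuat <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# translational / rotational diffusivities for one species under a drag rule
.speciesDiffusivities <- function(spec, ip) {
  d <- spec@effectiveDiameter
  if (ip@dragRule == "diameter") {
    Dt <- ip@referenceDiameter / d            # nm^2 / tau
    Dr <- 3 * Dt / d^2                        # rad^2 / tau (sphere relation)
  } else {
    Dt <- .kBT_J / (3 * pi * ip@viscosity * d * 1e-9) * 1e18  # nm^2 / s
    Dr <- .kBT_J / (pi * ip@viscosity * (d * 1e-9)^3)         # rad^2 / s
  }
  c(Dt = Dt, Dr = Dr)
}

.temperatureFactor <- function(group, ip) {
  tt <- ip@temperatures
  if (group %in% names(tt)) unname(tt[[group]])
  else if ("default" %in% names(tt)) unname(tt[["default"]])
  else 1
}

# species definitions in the form the kernel expects
.speciesForEngine <- function(comp, ip) {
  lapply(comp@species, function(s) {
    D <- .speciesDiffusivities(s, ip)
    type <- match(s@siteType, c("none", "A", "B")) - 1L
    list(body_off = s@bodyOffsets, body_rad = s@bodyDiameters / 2,
         site_off = s@siteOffsets, site_rad = s@siteDiameter / 2,
         site_type = type, Dt = unname(D["Dt"]), Dr = unname(D["Dr"]),
         Tfac = .temperatureFactor(s@temperatureGroup, ip),
         rotate = valence(s) > 0 || length(s@bodyDiameters) > 1)
  })
}

# maximal reach of a species from its centre (sphere surfaces)
.speciesExtent <- function(s) {
  max(sqrt(colSums(s@bodyOffsets^2)) + s@bodyDiameters / 2)
}

# world-frame repulsion-sphere centres and radii for a state
.worldSpheres <- function(state) {
  comp <- state@composition
  out <- lapply(seq_len(nParticles(state)), function(i) {
    s <- comp@species[[state@speciesIndex[i]]]
    off <- if (ncol(s@bodyOffsets) > 1 || any(s@bodyOffsets != 0))
      .qrotate(state@quaternions[i, ], s@bodyOffsets) else s@bodyOffsets
    cbind(t(off + state@positions[i, ]), s@bodyDiameters / 2)
  })
  do.call(rbind, out)
}

#' Soft quartic pair repulsion with XPLOR smoothing
#'
#' Evaluates the pair potential used between all excluded-volume spheres,
#' \eqn{U(r) = \epsilon_{soft}(1-(r/r_{cut})^4)} for \eqn{r<r_{cut}} and 0
#' beyond, multiplied on \eqn{[r_{on}, r_{cut}]} by the XPLOR smoothing
#' function so that energy and force go continuously to zero at the cutoff.
#'
#' @param r separation(s), nm
#' @param sigma contact distance \eqn{r_{cut}} (sum of sphere radii), nm
#' @param params a \linkS4class{ForceFieldParams}
#' @param smooth apply the smoothing window (disable to obtain the bare
#'   quartic form)
#' @return data.frame with columns \code{r}, \code{energy} (kBT) and
#'   \code{force} (kBT/nm, positive = repulsive)
#' @export
softRepulsion <- function(r, sigma, params = ForceFieldParams(),
                          smooth = TRUE) {
  out <- .engine_soft_pair(as.numeric(r), sigma, params@epsSoft,
                           params@rOnFrac, smooth)
  data.frame(r = as.numeric(r), energy = out$energy, force = out$force)
}

#' Place a composition on a CsCl-type lattice
#'
#' Particles are assigned to the two interpenetrating cubic sublattices of a
#' CsCl arrangement spanning the box, in an order shuffled deterministically
#' by \code{seed}; anisotropic species receive random orientations.  The
#' arrangement guarantees a minimum pair distance of \eqn{\sqrt{3}/2} times
#' the cell edge, and the function refuses compositions whose largest
#' species pair cannot fit at that spacing.
#'
#' @param comp a \linkS4class{SystemComposition}
#' @param seed RNG seed for the species shuffle and orientations
#' @return a \linkS4class{SystemState} at time 0
#' @export
initializeLattice <- function(comp, seed = 1) {
  counts <- comp@counts
  n <- sum(counts)
  edge <- comp@box@edgeLengths[1]
  spIdx <- rep(seq_along(counts), counts)
  if (n == 0)
    return(new("SystemState", composition = comp, speciesIndex = integer(),
               positions = matrix(0, 0, 3), quaternions = matrix(0, 0, 4),
               bonds = matrix(0L, 0, 4), time = 0))
  m <- ceiling((n / 2)^(1 / 3))
  a <- edge / m
  ext <- vapply(comp@species, .speciesExtent, 0)[unique(spIdx)]
  maxContact <- 2 * max(ext)
  if (sqrt(3) / 2 * a < maxContact)
    stop(sprintf(paste("initializeLattice: composition does not fit:",
                       "lattice spacing %.3g nm < required contact %.3g nm"),
                 sqrt(3) / 2 * a, maxContact))
  g <- expand.grid(i = seq_len(m) - 1, j = seq_len(m) - 1, k = seq_len(m) - 1)
  corner <- as.matrix(g) * a + 0.25 * a - edge / 2
  center <- as.matrix(g) * a + 0.75 * a - edge / 2
  sites <- rbind(corner, center)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pick <- sample.int(nrow(sites), n)
  pos <- sites[pick, , drop = FALSE]
  quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  rot <- vapply(comp@species, function(s)
    valence(s) > 0 || length(s@bodyDiameters) > 1, TRUE)[spIdx]
  if (any(rot)) quat[rot, ] <- .randomQuat(sum(rot))
  dimnames(pos) <- NULL
  new("SystemState", composition = comp, speciesIndex = as.integer(spIdx),
      positions = pos, quaternions = quat, bonds = matrix(0L, 0, 4), time = 0)
}

#' Number of crowder spheres realising a volume fraction
#'
#' @param phi target volume fraction
#' @param box a \linkS4class{SimulationBox}
#' @param diameter crowder diameter, nm
#' @return integer count \code{round(phi V / (pi d^3 / 6))}
#' @export
crowderCount <- function(phi, box, diameter = 30) {
  round(phi * boxVolume(box) / (pi * diameter^3 / 6))
}

#' Insert inert crowders by random sequential insertion
#'
#' Adds non-overlapping crowder spheres up to the requested volume fraction.
#' Direct insertion is attempted only up to phi = 0.35; beyond that the
#' random-sequential-insertion process stalls and the compression path
#' (dilute insertion in a large box followed by
#' \code{\link{compressToTarget}}) must be used instead.
#'
#' @param state a \linkS4class{SystemState} whose composition has a
#'   "crowder" species slot
#' @param phi target crowder volume fraction
#' @param diameter crowder diameter, nm
#' @param seed RNG seed for the insertion sequence
#' @param maxAttempts insertion attempts before giving up
#' @return the state with crowders appended
#' @export
insertCrowders <- function(state, phi, diameter = 30, seed = 1,
                           maxAttempts = 5e7) {
  if (phi < 0) stop("insertCrowders: phi must be >= 0")
  if (phi == 0) return(state)
  if (phi > 0.35)
    stop("insertCrowders: direct insertion supported only for phi <= 0.35; ",
         "insert in an expanded box and use compressToTarget()")
  comp <- state@composition
  ci <- match("crowder", names(comp@species))
  if (is.na(ci)) stop("insertCrowders: composition has no 'crowder' species")
  box <- comp@box
  n <- crowderCount(phi, box, diameter)
  if (n == 0) return(state)
  sph <- .worldSpheres(state)
  if (is.null(sph)) sph <- matrix(0, 0, 4)
  newpos <- .engine_rsi(sph[, 1:3, drop = FALSE], sph[, 4], n, diameter / 2,
                        box@edgeLengths, box@boundaryMode == "periodic",
                        seed, maxAttempts)
  comp@counts[ci] <- comp@counts[ci] + n
  new("SystemState", composition = comp,
      speciesIndex = c(state@speciesIndex, rep(as.integer(ci), n)),
      positions = rbind(state@positions, newpos),
      quaternions = rbind(state@quaternions,
                          matrix(rep(c(1, 0, 0, 0), each = n), n, 4)),
      bonds = state@bonds, time = state@time)
}

.emptyBondingParams <- function()
  BondingParams(kon = 0, koff = 0, updaterPeriod = 1)

# assemble kernel arguments and run; shared by the public entry points
.runKernel <- function(state, ip, ff, bp, nSteps, stride, integrate,
                       logEvents, boxFinal, compressSteps, seed,
                       updaterOff = FALSE, countEvery = 1) {
  comp <- state@composition
  box <- comp@box
  if (is.null(bp)) bp <- .emptyBondingParams()
  dt <- ip@dt
  n <- bp@updaterPeriod
  if (bp@javaMode) {
    pOn <- if (bp@kon > 0) 1.0 else 0.0  # diffusion-limited: bind on contact
    pOff <- perInvocationProbability(bp@koff, n, dt)
    metropolis <- FALSE
    escape <- TRUE
  } else {
    pOn <- perInvocationProbability(bp@kon, n, dt)
    pOff <- perInvocationProbability(bp@koff, n, dt)
    metropolis <- TRUE
    escape <- FALSE
  }
  if (updaterOff) { pOn <- 0; pOff <- 0 }
  if (pOn == 0 && pOff == 0 && nrow(state@bonds) == 0) n <- 0
  res <- .engine_run(
    species = .speciesForEngine(comp, ip),
    sp_of = state@speciesIndex, pos0 = state@positions,
    quat0 = state@quaternions,
    bonds0 = matrix(as.integer(state@bonds), nrow(state@bonds), 4),
    box = box@edgeLengths, periodic = box@boundaryMode == "periodic",
    walls = box@boundaryMode == "walled", dt = dt, n_steps = as.integer(nSteps),
    stride = as.integer(stride), eps_soft = ff@epsSoft,
    r_on_frac = ff@rOnFrac, P_on = pOn, P_off = pOff,
    updater_period = as.integer(n), d_bind = bp@dBind,
    bind_center = bp@bindCriterion == "center", spring_k = bp@bondSpringK,
    rest_len = bp@bondRestLength, frustration = bp@frustration,
    java_escape = escape, metropolis = metropolis, integrate = integrate,
    seed = seed, box_final = boxFinal,
    compress_steps = as.integer(compressSteps), log_events = logEvents,
    max_step_frac = ip@maxStepFrac, count_every = as.integer(countEvery))
  finalBox <- SimulationBox(res$box, box@boundaryMode)
  comp@box <- finalBox
  finalState <- new("SystemState", composition = comp,
                    speciesIndex = state@speciesIndex, positions = res$final_pos,
                    quaternions = res$final_quat,
                    bonds = matrix(as.integer(res$final_bonds),
                                   nrow(res$final_bonds), 4),
                    time = state@time + nSteps * dt)
  ev <- matrix(as.integer(res$events), nrow(res$events), 6)
  colnames(ev) <- c("step", "event", "molecule_a", "site_a", "molecule_b",
                    "site_b")
  new("SimTrajectory",
      framePositions = res$frame_pos, frameBonds = res$frame_bonds,
      frameTimes = state@time + res$frame_steps * dt,
      bondCountTimes = state@time + res$bond_count_steps * dt,
      bondCounts = as.numeric(res$bond_counts), finalState = finalState,
      events = ev, dt = dt)
}

#' Run the Brownian-dynamics engine
#'
#' Propagates a \linkS4class{SystemState} for \code{nSteps} steps, invoking
#' the dynamic-bond updater every \code{bp@updaterPeriod} steps (omit
#' \code{bp} for a bonding-free run).  Frames (positions plus the live bond
#' edge list) are recorded every \code{stride} steps; \code{stride = 0}
#' stores only the initial and final configurations.  Identical inputs and
#' seed reproduce the trajectory exactly.
#'
#' @param state starting \linkS4class{SystemState}
#' @param ip \linkS4class{IntegratorParams}
#' @param ff \linkS4class{ForceFieldParams}
#' @param bp \linkS4class{BondingParams} or NULL
#' @param nSteps number of integration steps (0 records the initial frame
#'   only)
#' @param stride frame-recording stride in steps
#' @param integrate set FALSE to freeze all positions and run only the bond
#'   updater (used for updater statistics and rate measurements)
#' @param logEvents record every bond formation/breakage event
#' @param countEvery record the bond count every this many updater calls
#' @param seed RNG seed for this run (defaults to \code{ip@seed})
#' @return a \linkS4class{SimTrajectory}
#' @export
runSimulation <- function(state, ip, ff = ForceFieldParams(), bp = NULL,
                          nSteps = 1000, stride = 0, integrate = TRUE,
                          logEvents = FALSE, countEvery = 1, seed = ip@seed) {
  .runKernel(state, ip, ff, bp, nSteps, stride, integrate, logEvents,
             boxFinal = state@composition@box@edgeLengths, compressSteps = 0L,
             seed = seed, countEvery = countEvery)
}

#' Advance a state by a single integration step
#'
#' @inheritParams runSimulation
#' @return the advanced \linkS4class{SystemState}
#' @export
langevinStep <- function(state, ip, ff = ForceFieldParams(), seed = ip@seed) {
  runSimulation(state, ip, ff, bp = NULL, nSteps = 1, seed = seed)@finalState
}

#' Compress the box linearly to a target edge
#'
#' Interpolates the box edge linearly over the schedule while integrating,
#' rescaling particle centres affinely with the box; bonding is off during
#' compression and is switched on afterwards by running the compressed
#' state.  Used to reach crowder volume fractions beyond the direct
#' random-sequential-insertion regime.
#'
#' @param state a \linkS4class{SystemState} whose box matches the schedule's
#'   initial edge
#' @param sched a \linkS4class{CompressionSchedule}
#' @param ip,ff integrator and force-field parameters
#' @param seed RNG seed
#' @return the compressed \linkS4class{SystemState}
#' @export
compressToTarget <- function(state, sched, ip, ff = ForceFieldParams(),
                             seed = ip@seed) {
  edge <- state@composition@box@edgeLengths[1]
  if (abs(edge - sched@initialEdge) > 1e-6)
    stop("compressToTarget: state box does not match the schedule")
  if (sched@initialEdge == sched@targetEdge) return(state)
  tr <- .runKernel(state, ip, ff, bp = NULL, nSteps = sched@nSteps,
                   stride = 0, integrate = TRUE, logEvents = FALSE,
                   boxFinal = rep(sched@targetEdge, 3),
                   compressSteps = sched@nSteps, seed = seed)
  tr@finalState
}

#' Bond-count time series of a run
#'
#' @param traj a \linkS4class{SimTrajectory}
#' @return data.frame with columns \code{time} and \code{bonds}
#' @export
bondCountSeries <- function(traj)
  data.frame(time = traj@bondCountTimes, bonds = traj@bondCounts)

#' Measured crowder volume fraction of a state
#'
#' @param state a \linkS4class{SystemState}
#' @return the volume of all crowder spheres over the box volume
#' @export
measuredVolumeFraction <- function(state) {
  comp <- state@composition
  ci <- match("crowder", names(comp@species))
  if (is.na(ci)) return(0)
  d <- comp@species[[ci]]@bodyDiameters[1]
  sum(state@speciesIndex == ci) * pi * d^3 / 6 / boxVolume(comp@box)
}
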