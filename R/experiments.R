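# Scripted reduced-scale reproductions of the in-silico experiments:
# crowding sweep, crowder-activity sweep, and the monovalent Kd sweep.

#' Plan for a sweep experiment
#'
#' @slot preset engine preset name
#' @slot sweepVariable "phi" (crowder volume fraction) or
#'   "crowderTemperature" (crowder effective temperature factor)
#' @slot values sweep values
#' @slot seeds replicate seeds (default five replicates)
#' @slot scale copy-number/box desk-scale factor; concentrations and
#'   crowder volume fractions are preserved exactly
#' @slot nSteps run length in steps
#' @slot stride frame-recording stride in steps
#' @slot koff dissociation rate (NA uses the preset default)
#' @export
setClass("ExperimentPlan", representation(
  preset = "character", sweepVariable = "character", values = "numeric",
  seeds = "numeric", scale = "numeric", nSteps = "numeric",
  stride = "numeric", koff = "numeric"))

setValidity("ExperimentPlan", function(object) {
  msg <- character()
  if (!object@sweepVariable %in% c("phi", "crowderTemperature"))
    msg <- c(msg, "sweepVariable must be 'phi' or 'crowderTemperature'")
  if (object@scale <= 0 || object@scale > 1)
    msg <- c(msg, "scale must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param preset,sweepVariable,values,seeds,scale,nSteps,stride,koff see
#'   slots
#' @rdname ExperimentPlan-class
#' @export
ExperimentPlan <- function(preset = "hoomd_style", sweepVariable = "phi",
                           values = c(0, 0.35, 0.5), seeds = 1:5,
                           scale = 1 / 8, nSteps = 2.5e5, stride = 5e3,
                           koff = NA_real_) {
  new("ExperimentPlan", preset = preset, sweepVariable = sweepVariable,
      values = values, seeds = seeds, scale = scale, nSteps = nSteps,
      stride = stride, koff = koff)
}

#' @export
setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf("ExperimentPlan (%s): %s in {%s}, %d seeds, scale %.3g, %g steps\n",
              object@preset, object@sweepVariable,
              paste(object@values, collapse = ", "), length(object@seeds),
              object@scale, object@nSteps))
})

# provenance block attached to every report
.planProvenance <- function(plan) {
  list(preset = plan@preset, sweepVariable = plan@sweepVariable,
       values = plan@values, seeds = plan@seeds, scale = plan@scale,
       nSteps = plan@nSteps, stride = plan@stride, koff = plan@koff,
       package = as.character(utils::packageVersion("synDropSim")),
       presetHash = sum(utf8ToInt(paste(
         unlist(presetValues(plan@preset)), collapse = ""))))
}

#' Run one assembly condition (full multivalent system)
#'
#' Builds the desk-scaled composition, inserts crowders (direct insertion
#' up to phi = 0.35, the expanded-box compression path beyond), runs the
#' engine with dynamic bonding, and reduces the trajectory to cluster
#' statistics.
#'
#' @param preset preset name
#' @param phi crowder volume fraction
#' @param crowderTemperature crowder effective temperature factor
#' @param scale desk-scale factor
#' @param seed replicate seed
#' @param nSteps,stride run length and frame stride (steps)
#' @param koff dissociation rate (NULL: preset default)
#' @param powerLawWindow time window for the growth-exponent fit (NULL:
#'   first half of the run)
#' @return list: \code{kinetics} (data.frame time/largest/mean),
#'   \code{alpha} (growth exponent or NA), \code{diffusivities}
#'   (cluster D-vs-size table), \code{finalPartition}, \code{traj}
#' @export
runAssemblyCondition <- function(preset = "hoomd_style", phi = 0,
                                 crowderTemperature = 1, scale = 1 / 8,
                                 seed = 1, nSteps = 2.5e5, stride = 5e3,
                                 koff = NULL, powerLawWindow = NULL) {
  comp <- presetComposition(preset, scale = scale)
  state <- initializeLattice(comp, seed = seed)
  ip <- presetIntegrator(preset, crowderTemperature = crowderTemperature,
                         seed = seed)
  ff <- presetForceField(preset)
  bp <- presetBonding(preset, koff = koff)
  if (phi > 0.35) {
    # dilute insertion in the expanded box, then linear compression
    sched <- presetCompression(preset, scale = scale)
    big <- comp
    big@box <- SimulationBox(rep(sched@initialEdge, 3),
                             comp@box@boundaryMode)
    state <- initializeLattice(big, seed = seed)
    phiBig <- phi * (sched@targetEdge / sched@initialEdge)^3
    state <- insertCrowders(state, phiBig, seed = seed + 7919)
    # fix the crowder count to realise phi exactly in the target box
    nTarget <- crowderCount(phi, SimulationBox(sched@targetEdge))
    nHave <- sum(particleSpecies(state) == "crowder")
    if (nHave < nTarget) {
      dphi <- (nTarget - nHave) * pi * 30^3 / 6 / boxVolume(state@composition@box)
      state <- insertCrowders(state, dphi, seed = seed + 15817)
    }
    state <- compressToTarget(state, sched, ip, ff, seed = seed)
  } else if (phi > 0) {
    state <- insertCrowders(state, phi, seed = seed + 7919)
  }
  traj <- runSimulation(state, ip, ff, bp, nSteps = nSteps, stride = stride,
                        countEvery = 10, seed = seed)
  parts <- trajectoryClusters(traj)
  kin <- sizeKinetics(parts, traj@frameTimes)
  if (is.null(powerLawWindow))
    powerLawWindow <- c(0, max(traj@frameTimes) / 2)
  alpha <- tryCatch(
    fitPowerLaw(kin$time, kin$mean, window = powerLawWindow)$alpha,
    error = function(e) NA_real_)
  dtFrame <- diff(traj@frameTimes[1:2])
  box <- traj@finalState@composition@box
  tracks <- linkClusters(parts, traj@framePositions, traj@frameTimes, box)
  dd <- clusterDiffusivities(tracks, dt = dtFrame, box = box)
  list(kinetics = kin, alpha = alpha, diffusivities = dd,
       finalPartition = parts[[length(parts)]], traj = traj)
}

.sweepCore <- function(plan, runFun) {
  rows <- list()
  details <- list()
  for (v in plan@values) for (s in plan@seeds) {
    res <- tryCatch(runFun(v, s), error = function(e) e)
    key <- sprintf("%g_%d", v, s)
    if (inherits(res, "error")) {
      warning(sprintf("condition %s seed %d failed: %s", format(v), s,
                      conditionMessage(res)))
      next
    }
    details[[key]] <- res$detail
    rows[[key]] <- res$row
  }
  list(summary = do.call(rbind, rows), details = details,
       provenance = .planProvenance(plan))
}

#' Crowding sweep: assembly statistics versus crowder volume fraction
#'
#' @param plan an \linkS4class{ExperimentPlan} with
#'   \code{sweepVariable = "phi"}
#' @return report list: \code{summary} (one row per condition x seed with
#'   final largest/mean cluster size, growth exponent alpha and the
#'   D-vs-size slope when estimable), \code{details} (kinetics tables),
#'   \code{provenance}
#' @export
runCrowdingSweep <- function(plan = ExperimentPlan()) {
  stopifnot(plan@sweepVariable == "phi")
  koff <- if (is.na(plan@koff)) NULL else plan@koff
  .sweepCore(plan, function(v, s) {
    res <- runAssemblyCondition(plan@preset, phi = v, scale = plan@scale,
                                seed = s, nSteps = plan@nSteps,
                                stride = plan@stride, koff = koff)
    kin <- res$kinetics
    slope <- tryCatch(
      sizeScalingFit(res$diffusivities$size, res$diffusivities$D)$slope,
      error = function(e) NA_real_)
    list(row = data.frame(
           phi = v, seed = s, largestFinal = tail(kin$largest, 1),
           meanFinal = tail(kin$mean, 1), alpha = res$alpha,
           dSizeSlope = slope, nClusters = tail(kin$nClusters, 1)),
         detail = kin)
  })
}

#' Activity sweep: assembly statistics versus crowder effective temperature
#'
#' Runs at fixed crowder volume fraction (default 30 percent) while the
#' crowder thermostat is varied; the synDrop components stay thermal.
#'
#' @param plan an \linkS4class{ExperimentPlan} with
#'   \code{sweepVariable = "crowderTemperature"}
#' @param phi fixed crowder volume fraction
#' @return report list as in \code{\link{runCrowdingSweep}}
#' @export
runActivitySweep <- function(plan = ExperimentPlan(
                               sweepVariable = "crowderTemperature",
                               values = c(0.5, 1, 2)), phi = 0.30) {
  stopifnot(plan@sweepVariable == "crowderTemperature")
  koff <- if (is.na(plan@koff)) NULL else plan@koff
  .sweepCore(plan, function(v, s) {
    res <- runAssemblyCondition(plan@preset, phi = phi,
                                crowderTemperature = v, scale = plan@scale,
                                seed = s, nSteps = plan@nSteps,
                                stride = plan@stride, koff = koff)
    kin <- res$kinetics
    slope <- tryCatch(
      sizeScalingFit(res$diffusivities$size, res$diffusivities$D)$slope,
      error = function(e) NA_real_)
    list(row = data.frame(
           crowderTemperature = v, seed = s,
           largestFinal = tail(kin$largest, 1),
           meanFinal = tail(kin$mean, 1), alpha = res$alpha,
           dSizeSlope = slope),
         detail = kin)
  })
}

#' Monovalent Kd sweep versus crowder volume fraction
#'
#' For each volume fraction and seed, measures the effective dissociation
#' constant from the monovalent system; optionally follows each
#' equilibrated state with a binding-switched-off decay to measure koff.
#'
#' @param plan an \linkS4class{ExperimentPlan} with
#'   \code{sweepVariable = "phi"} (values are volume fractions)
#' @param nStepsEq equilibration steps per run
#' @param measureKoff also measure the dissociation rate by decay
#' @param nStepsDecay decay steps for the koff measurement
#' @param countEvery bond-count recording stride (updater calls)
#' @return report list: \code{summary} (phi, seed, Kd, Neq, koff, koffLo,
#'   koffHi), \code{provenance}
#' @export
runKdSweep <- function(plan = ExperimentPlan(values = c(0, 0.30),
                                             nSteps = NA),
                       nStepsEq = 1.6e6, measureKoff = FALSE,
                       nStepsDecay = 8e5, countEvery = 100) {
  stopifnot(plan@sweepVariable == "phi")
  koff <- if (is.na(plan@koff)) NULL else plan@koff
  .sweepCore(plan, function(v, s) {
    kd <- measureEffectiveKd(plan@preset, phi = v, scale = plan@scale,
                             seed = s, nSteps = nStepsEq,
                             countEvery = countEvery, koff = koff)
    row <- data.frame(phi = v, seed = s, Kd = kd$Kd, Neq = kd$Neq,
                      koff = NA_real_, koffLo = NA_real_, koffHi = NA_real_)
    if (measureKoff) {
      dec <- tryCatch(
        measureKoffDecay(kd$finalState, plan@preset, nSteps = nStepsDecay,
                         countEvery = countEvery, seed = s + 31,
                         minBonds = 5),
        error = function(e) NULL)
      if (!is.null(dec)) {
        row$koff <- dec$koff; row$koffLo <- dec$ci[1]; row$koffHi <- dec$ci[2]
      }
    }
    list(row = row, detail = kd$series)
  })
}

#' Write a sweep report to disk
#'
#' @param report a report list from one of the sweep runners
#' @param dir output directory (created if needed)
#' @param name base file name
#' @return invisibly, the paths written (summary CSV + provenance JSON)
#' @export
writeReport <- function(report, dir, name = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, "_summary.csv"))
  js <- file.path(dir, paste0(name, "_provenance.json"))
  write.csv(report$summary, csv, row.names = FALSE)
  jsonlite::write_json(report$provenance, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
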