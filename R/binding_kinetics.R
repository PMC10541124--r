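# Effective equilibrium and rate constants from monovalent simulations.
#
# The dissociation constant of the inducible heterodimer interaction is
# measured in a reduced system where each component carries exactly one
# binding site, so only the dimerisation reaction A + B <-> AB can occur.
# Bond-count kinetics then give the equilibrium bond number, and Kd follows
# from the law of mass action in the simulation box.

#' Monovalent composition used to measure the dissociation constant
#'
#' 200 + 200 monovalent hexamer/dimer components in a 400-nm cubic box (the
#' 1:1 stoichiometric system); \code{scale} shrinks copy numbers at fixed
#' concentration.
#'
#' @param preset "hoomd_style" or "java_style"
#' @param scale copy-number scale factor
#' @return a \linkS4class{SystemComposition}
#' @export
buildMonomericSystem <- function(preset = c("hoomd_style", "java_style"),
                                 scale = 1) {
  presetComposition(match.arg(preset), monomeric = TRUE, scale = scale)
}

#' Equilibrium bond number from a saturating-exponential fit
#'
#' Fits \eqn{N(t) = N_{eq}(1 - e^{-t/t_{relax}})} to a rising bond-count
#' series (the equivalent exponential decay of the unbound pool) and
#' returns the plateau.  A constant series returns its mean with zero
#' relaxation time.  The last 20 percent of the series is checked for
#' residual drift; \code{equilibrated} is FALSE when the drift exceeds one
#' standard deviation of the fluctuations in that window.
#'
#' @param time,bonds the bond-count series
#' @return list: \code{Neq}, \code{tRelax}, \code{equilibrated},
#'   \code{fitted} (function of t), \code{converged}
#' @export
fitEquilibriumBonds <- function(time, bonds) {
  stopifnot(length(time) == length(bonds))
  if (length(time) < 10)
    stop("fitEquilibriumBonds: need at least 10 time points")
  if (sd(bonds) < 1e-12)
    return(list(Neq = mean(bonds), tRelax = 0, equilibrated = TRUE,
                fitted = function(t) rep(mean(bonds), length(t)),
                converged = TRUE))
  t0 <- min(time)
  tt <- time - t0
  neq0 <- mean(tail(bonds, max(3, length(bonds) %/% 5)))
  # initial relaxation guess: first crossing of (1 - 1/e) of the plateau
  idx <- which(bonds >= (1 - exp(-1)) * neq0)[1]
  tr0 <- if (is.na(idx) || tt[idx] <= 0) max(tt) / 5 else tt[idx]
  fit <- tryCatch(
    suppressWarnings(
      nls(bonds ~ Neq * (1 - exp(-tt / tr)),
          start = list(Neq = max(neq0, 1e-6), tr = max(tr0, 1e-12)),
          control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to a coarse grid + golden refinement on tr, Neq analytic
    sse <- function(tr) {
      f <- 1 - exp(-tt / tr)
      neq <- sum(bonds * f) / sum(f^2)
      sum((bonds - neq * f)^2)
    }
    trs <- exp(seq(log(max(min(diff(tt)), 1e-12)), log(max(tt) * 2),
                   length.out = 60))
    tr <- trs[which.min(vapply(trs, sse, 0))]
    f <- 1 - exp(-tt / tr)
    neq <- sum(bonds * f) / sum(f^2)
    pars <- c(Neq = neq, tr = tr)
    conv <- FALSE
  } else {
    pars <- coef(fit)
    conv <- TRUE
  }
  tailwin <- tt >= quantile(tt, 0.8)
  drift <- abs(coef(lm(bonds[tailwin] ~ tt[tailwin]))[2]) *
    (max(tt) - quantile(tt, 0.8))
  noise <- sd(bonds[tailwin])
  # equilibrated when the residual drift over the last fifth of the run is
  # below the fluctuation scale (with a 0.5% relative floor for noiseless
  # series)
  list(Neq = unname(pars["Neq"]), tRelax = unname(pars["tr"]),
       equilibrated = is.finite(drift) &&
         drift < max(noise, 0.005 * abs(unname(pars["Neq"])), 1e-12),
       fitted = function(t) unname(pars["Neq"]) *
         (1 - exp(-(t - t0) / unname(pars["tr"]))),
       converged = conv)
}

#' Effective dissociation constant of the dimerisation reaction
#'
#' For A + B <-> AB at equilibrium in a box of volume V,
#' \eqn{K_d = [A][B]/[AB] = N_A N_B / (N_{AB} N_{Av} V)}.
#'
#' @param nA,nB free molecule counts at equilibrium
#' @param nAB bound pair count at equilibrium
#' @param volume box volume in nm^3
#' @return Kd in micromolar; \code{nAB = 0} returns \code{Inf} with a
#'   warning carrying the detection floor (the Kd that a single bound pair
#'   would have produced)
#' @export
effectiveKd <- function(nA, nB, nAB, volume) {
  if (nA < 0 || nB < 0 || nAB < 0) stop("effectiveKd: negative counts")
  vl <- volume * 1e-24
  if (nAB == 0) {
    floorKd <- nA * nB / (1 * .NAvogadro * vl) * 1e6
    warning(sprintf(
      "effectiveKd: no bound pairs; Kd above detection floor %.3g uM", floorKd))
    return(Inf)
  }
  nA * nB / (nAB * .NAvogadro * vl) * 1e6
}

#' Dissociation rate from a bond-decay series
#'
#' After switching binding off (\code{\link{switchOffBinding}}) the bond
#' count is a pure death process, \eqn{N(t) = N_0 e^{-k_{off} t}} in
#' expectation.  The maximum-likelihood rate is the number of observed
#' dissociation events over the integrated bond-time,
#' \eqn{\hat k = (N_0 - N_T) / \int N \, dt}, with the Poisson 95 percent
#' interval \eqn{\hat k (1 \pm 1.96/\sqrt{events})}.
#'
#' @param time,bonds the decaying series
#' @param minBonds required initial bond count for useful statistical power
#' @return list: \code{koff}, \code{ci} (95 percent), \code{N0},
#'   \code{events}
#' @export
measureKoff <- function(time, bonds, minBonds = 50) {
  stopifnot(length(time) == length(bonds))
  if (bonds[1] < minBonds)
    stop("measureKoff: fewer than ", minBonds,
         " initial bonds; rate estimate underpowered")
  events <- bonds[1] - bonds[length(bonds)]
  if (events <= 0)
    return(list(koff = 0, ci = c(0, 0), N0 = bonds[1], events = 0))
  # trapezoidal integrated bond-time
  exposure <- sum(diff(time) * (head(bonds, -1) + tail(bonds, -1)) / 2)
  k <- events / exposure
  ci <- k * (1 + c(-1.96, 1.96) / sqrt(events))
  list(koff = k, ci = ci, N0 = bonds[1], events = events)
}

#' Association rate constant from koff and Kd
#'
#' @param koff dissociation rate (1/time)
#' @param kd dissociation constant in micromolar
#' @return kon in 1/(M * time unit)
#' @export
inferKon <- function(koff, kd) {
  if (kd <= 0) stop("inferKon: Kd must be positive")
  koff / (kd * 1e-6)
}

#' Measure the effective Kd of a preset's monovalent system end to end
#'
#' Builds the monovalent composition, places it on the lattice, optionally
#' inserts crowders, runs the engine to (near) equilibrium, fits the
#' bond-count plateau and evaluates the mass-action Kd.
#'
#' @param preset "hoomd_style" or "java_style"
#' @param phi crowder volume fraction (direct insertion, <= 0.35)
#' @param scale copy-number scale factor
#' @param seed RNG seed for lattice, insertion and dynamics
#' @param nSteps integration steps
#' @param countEvery record the bond count every this many updater calls
#' @param koff override the preset dissociation rate
#' @return list: \code{Kd} (uM), \code{Neq}, \code{nTotal}, \code{series}
#'   (bond-count data.frame), \code{fit}, \code{finalState}
#' @export
measureEffectiveKd <- function(preset = c("hoomd_style", "java_style"),
                               phi = 0, scale = 1, seed = 1,
                               nSteps = 2e6, countEvery = 50, koff = NULL) {
  preset <- match.arg(preset)
  comp <- buildMonomericSystem(preset, scale)
  state <- initializeLattice(comp, seed = seed)
  if (phi > 0) state <- insertCrowders(state, phi, seed = seed + 7919)
  ip <- presetIntegrator(preset, seed = seed)
  bp <- presetBonding(preset, koff = koff)
  ff <- presetForceField(preset)
  tr <- runSimulation(state, ip, ff, bp, nSteps = nSteps, stride = 0,
                      countEvery = countEvery, seed = seed)
  ser <- bondCountSeries(tr)
  fit <- fitEquilibriumBonds(ser$time, ser$bonds)
  nTot <- unname(state@composition@counts["hexamer"])
  # on short, noisy series the two-parameter fit can run away; fall back to
  # the tail mean of the series when the fitted plateau is not interior
  neqTail <- mean(ser$bonds[ser$time >= quantile(ser$time, 0.6)])
  neq <- fit$Neq
  if (!is.finite(neq) || neq >= nTot || neq > 1.5 * max(ser$bonds))
    neq <- neqTail
  neq <- min(max(neq, 0), nTot - 1e-9)
  kd <- effectiveKd(nTot - neq, nTot - neq, neq,
                    boxVolume(comp@box))
  list(Kd = kd, Neq = neq, nTotal = nTot, series = ser, fit = fit,
       finalState = tr@finalState)
}

#' Measure the dissociation rate by switching binding off
#'
#' Starting from an equilibrated state, sets the binding rate to zero and
#' fits the exponential decay of the bond count.
#'
#' @param state an equilibrated \linkS4class{SystemState} with bonds
#' @param preset preset name (supplies integrator/bonding parameters)
#' @param nSteps decay steps
#' @param countEvery bond-count recording stride in updater calls
#' @param seed RNG seed
#' @param minBonds passed to \code{\link{measureKoff}}
#' @return list from \code{\link{measureKoff}} plus the decay \code{series}
#' @export
measureKoffDecay <- function(state, preset = c("hoomd_style", "java_style"),
                             nSteps = 1e6, countEvery = 50, seed = 1,
                             minBonds = 50) {
  preset <- match.arg(preset)
  ip <- presetIntegrator(preset, seed = seed)
  bp <- switchOffBinding(presetBonding(preset))
  ff <- presetForceField(preset)
  tr <- runSimulation(state, ip, ff, bp, nSteps = nSteps, stride = 0,
                      countEvery = countEvery, seed = seed)
  ser <- bondCountSeries(tr)
  out <- measureKoff(ser$time, ser$bonds, minBonds = minBonds)
  out$series <- ser
  out
}
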