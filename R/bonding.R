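# Dynamic-bonding operations exposed at the R level.

#' Per-invocation probability of a rate-driven event
#'
#' The bond updater runs every \code{n} steps; a process with rate constant
#' \code{rate} then fires between consecutive invocations with probability
#' \eqn{P = 1 - \exp(-rate \cdot n \cdot dt)}.  In the small-P regime this
#' reduces to \eqn{rate \cdot n \cdot dt}, so measured event rates recover
#' the input rate constants.
#'
#' @param rate rate constant (1/time)
#' @param n updater period in steps
#' @param dt integration time step
#' @return probability in [0, 1)
#' @export
perInvocationProbability <- function(rate, n, dt) {
  if (any(rate < 0)) stop("perInvocationProbability: rate must be >= 0")
  1 - exp(-rate * n * dt)
}

#' World-frame binding-site positions of a state
#'
#' @param state a \linkS4class{SystemState}
#' @return data.frame: molecule, site, x, y, z, siteType, bound
#' @export
sitePositions <- function(state) {
  comp <- state@composition
  ip0 <- IntegratorParams()
  m <- .engine_site_positions(.speciesForEngine(comp, ip0),
                              state@speciesIndex, state@positions,
                              state@quaternions)
  df <- as.data.frame(m)
  df$siteType <- vapply(df$molecule, function(i)
    comp@species[[state@speciesIndex[i]]]@siteType, "")
  b <- state@bonds
  key <- paste(df$molecule, df$site)
  df$bound <- key %in% c(paste(b[, 1], b[, 2]), paste(b[, 3], b[, 4]))
  df
}

#' Candidate bonding pairs of a configuration
#'
#' All, and only, pairs of complementary free sites within the binding
#' range, exactly as enumerated by the engine's updater (minimum-image
#' distances; the two-bonds-per-molecule-pair frustration rule applied when
#' enabled).  Order is deterministic for a given state.
#'
#' @param state a \linkS4class{SystemState}
#' @param bp a \linkS4class{BondingParams}
#' @return data.frame: molecule_a, site_a, molecule_b, site_b
#' @export
findCandidatePairs <- function(state, bp) {
  comp <- state@composition
  m <- .engine_candidate_pairs(
    .speciesForEngine(comp, IntegratorParams()), state@speciesIndex,
    state@positions, state@quaternions,
    matrix(as.integer(state@bonds), nrow(state@bonds), 4),
    comp@box@edgeLengths, comp@box@boundaryMode == "periodic",
    bp@dBind, bp@bindCriterion == "center", bp@frustration)
  data.frame(molecule_a = m[, 1], site_a = m[, 2],
             molecule_b = m[, 3], site_b = m[, 4])
}

#' Apply one bond-updater invocation to a frozen configuration
#'
#' Runs the stochastic add/remove sweep once, without moving any particle:
#' existing bonds break with the per-invocation unbinding probability, and
#' candidate pairs (in randomly shuffled order, which resolves conflicts
#' when one site appears in several candidates) bind with the
#' per-invocation binding probability times the Metropolis acceptance for
#' the spring energy created.
#'
#' @param state a \linkS4class{SystemState}
#' @param bp a \linkS4class{BondingParams}
#' @param ip an \linkS4class{IntegratorParams} (supplies dt and seed)
#' @param seed RNG seed for this invocation
#' @return the updated \linkS4class{SystemState}
#' @export
bondUpdate <- function(state, bp, ip = IntegratorParams(), seed = ip@seed) {
  tr <- runSimulation(state, ip, ForceFieldParams(), bp,
                      nSteps = bp@updaterPeriod, stride = 0,
                      integrate = FALSE, seed = seed)
  tr@finalState
}

#' Site-occupancy check: every site participates in at most one bond
#'
#' @param state a \linkS4class{SystemState}
#' @return TRUE if the bond table respects single occupancy
#' @export
validBondTable <- function(state) {
  b <- state@bonds
  if (nrow(b) == 0) return(TRUE)
  keys <- c(paste(b[, 1], b[, 2]), paste(b[, 3], b[, 4]))
  !anyDuplicated(keys)
}
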