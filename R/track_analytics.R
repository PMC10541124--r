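# Trajectory statistics shared by simulated and experimental tracks.
#
# Tracks are long-format data.frames with columns track, frame, t, x, y
# (and optionally z and intensity).  Frames must be strictly increasing
# within a track; missing frames are gaps.  Lag statistics never span a
# gap: each track is split into gapless segments first.

.trackDims <- function(df) intersect(c("x", "y", "z"), names(df))

# split one track's rows into gapless segments (list of row-index vectors)
.gaplessSegments <- function(frames) {
  if (length(frames) == 0) return(list())
  brk <- c(0, cumsum(diff(frames) != 1))
  unname(split(seq_along(frames), brk))
}

#' Split a track table into per-track data.frames
#'
#' @param df track table (columns track, frame, t, x, y[, z, intensity])
#' @return named list of data.frames sorted by frame, each with attribute
#'   \code{hasGap}
#' @export
trackList <- function(df) {
  stopifnot(all(c("track", "frame") %in% names(df)))
  out <- lapply(split(df, df$track), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (anyDuplicated(tr$frame)) stop("trackList: duplicated frames in track")
    attr(tr, "hasGap") <- any(diff(tr$frame) != 1)
    tr
  })
  out
}

#' Keep only tracks with more than a minimum number of points
#'
#' The canonical filter for diffusivity statistics keeps trajectories with
#' more than 10 time points; the filter is idempotent.
#'
#' @param df track table
#' @param minPoints strict lower bound on points per track
#' @return filtered track table with attribute \code{nFiltered}
#' @export
filterTracks <- function(df, minPoints = 10) {
  n <- table(df$track)
  keep <- names(n)[n > minPoints]
  out <- df[df$track %in% keep, , drop = FALSE]
  attr(out, "nFiltered") <- length(n) - length(keep)
  out
}

# ensemble statistic machinery: for each track segment and lag, collect
# samples via `fun(seg_matrix, lag)` returning a numeric vector
.poolOverTracks <- function(df, lags, fun, minPoints = 0) {
  trs <- trackList(df)
  dims <- .trackDims(df)
  samples <- vector("list", length(lags))
  for (tr in trs) {
    if (nrow(tr) <= minPoints) next
    for (seg in .gaplessSegments(tr$frame)) {
      m <- as.matrix(tr[seg, dims, drop = FALSE])
      for (li in seq_along(lags)) {
        v <- fun(m, lags[li])
        if (length(v)) samples[[li]] <- c(samples[[li]], v)
      }
    }
  }
  samples
}

.curveFromSamples <- function(lags, samples, statistic, lagUnit) {
  vals <- vapply(samples, function(s) if (length(s)) mean(s) else NA_real_, 0)
  ns <- vapply(samples, length, 0L)
  se <- vapply(samples, function(s)
    if (length(s) > 1) sd(s) / sqrt(length(s)) else NA_real_, 0)
  new("CorrelationCurve", lags = as.numeric(lags), values = vals,
      counts = as.numeric(ns), se = se, statistic = statistic,
      lagUnit = lagUnit)
}

#' Time- and ensemble-averaged mean squared displacement
#'
#' @param df track table
#' @param maxLag largest lag in frames
#' @param minPoints tracks need strictly more than this many points
#'   (default: the more-than-10-points rule)
#' @return a \linkS4class{CorrelationCurve} (statistic "msd", lag in frames,
#'   values in squared position units)
#' @export
msdCurve <- function(df, maxLag = 10, minPoints = 10) {
  df <- filterTracks(df, minPoints)
  if (nrow(df) == 0) stop("msdCurve: no tracks pass the length filter")
  lags <- seq_len(maxLag)
  samples <- .poolOverTracks(df, lags, function(m, L) {
    n <- nrow(m)
    if (n <= L) return(numeric())
    d <- m[seq_len(n - L) + L, , drop = FALSE] - m[seq_len(n - L), , drop = FALSE]
    rowSums(d^2)
  })
  .curveFromSamples(lags, samples, "msd", "frames")
}

#' Diffusivity from an MSD curve
#'
#' Least-squares line through the origin over the fitted lags; in d
#' dimensions MSD(t) = 2 d D t, so free 2-d tracks use slope/4 and 3-d
#' tracks slope/6.
#'
#' @param curve a \linkS4class{CorrelationCurve} from \code{\link{msdCurve}}
#' @param dt frame interval (time units)
#' @param dim dimensionality of the tracks (2 or 3)
#' @param fitIntervals number of initial lags fitted
#' @return list: \code{D} in position-units^2 per time unit, \code{slope}
#' @export
fitDiffusivity <- function(curve, dt, dim = 2, fitIntervals = 10) {
  k <- seq_len(min(fitIntervals, length(curve@lags)))
  tl <- curve@lags[k] * dt
  ok <- is.finite(curve@values[k])
  slope <- sum(curve@values[k][ok] * tl[ok]) / sum(tl[ok]^2)
  list(D = slope / (2 * dim), slope = slope)
}

#' Angle correlation function of particle tracks
#'
#' For lag L, the cosine of the turning angle between the coarse-grained
#' displacement vectors x(t+L) - x(t) and x(t+2L) - x(t+L), averaged over
#' start times and tracks.  Values near -1 signal anti-persistent (caged or
#' confined) motion, near 0 free diffusion, near +1 persistent/driven
#' motion.  Zero-length displacements contribute no angle and are skipped.
#'
#' @param df track table
#' @param lags lags in frames
#' @param perTrack average within each track first, then across tracks
#'   (default pools all angle samples)
#' @param minPoints track length filter (strictly greater than)
#' @return a \linkS4class{CorrelationCurve} (statistic "angle_correlation")
#' @export
angleCorrelation <- function(df, lags = 1:10, perTrack = FALSE,
                             minPoints = 10) {
  df <- filterTracks(df, minPoints)
  if (nrow(df) == 0) stop("angleCorrelation: no tracks pass the length filter")
  sampler <- function(m, L) {
    n <- nrow(m)
    if (n < 2 * L + 1) return(numeric())
    i <- seq_len(n - 2 * L)
    u <- m[i + L, , drop = FALSE] - m[i, , drop = FALSE]
    v <- m[i + 2 * L, , drop = FALSE] - m[i + L, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ok <- nu > 0 & nv > 0
    if (!any(ok)) return(numeric())
    rowSums(u[ok, , drop = FALSE] * v[ok, , drop = FALSE]) / (nu[ok] * nv[ok])
  }
  if (!perTrack)
    return(.curveFromSamples(lags, .poolOverTracks(df, lags, sampler),
                             "angle_correlation", "frames"))
  trs <- trackList(df)
  dims <- .trackDims(df)
  perLag <- lapply(seq_along(lags), function(li) {
    means <- vapply(trs, function(tr) {
      s <- unlist(lapply(.gaplessSegments(tr$frame), function(seg)
        sampler(as.matrix(tr[seg, dims, drop = FALSE]), lags[li])))
      if (length(s)) mean(s) else NA_real_
    }, 0)
    means[is.finite(means)]
  })
  .curveFromSamples(lags, perLag, "angle_correlation", "frames")
}

#' Normalized velocity autocorrelation function of particle tracks
#'
#' Discrete frame-to-frame velocities v_i = (x_{i+1} - x_i)/dt; the curve is
#' C(L) = <v_i . v_{i+L}> averaged over start times and tracks, normalized
#' by C(0) so C(0) = 1.  A negative minimum at small lag is the signature of
#' elastic, anti-persistent motion.
#'
#' @param df track table
#' @param lags lags in frames (0 is always included for normalisation)
#' @param dt frame interval
#' @param normalize divide by C(0)
#' @param minPoints track length filter
#' @return a \linkS4class{CorrelationCurve} (statistic "vacf")
#' @export
velocityAutocorrelation <- function(df, lags = 0:10, dt = 1, normalize = TRUE,
                                    minPoints = 10) {
  df <- filterTracks(df, minPoints)
  if (nrow(df) == 0)
    stop("velocityAutocorrelation: no tracks pass the length filter")
  lags <- sort(unique(c(0, lags)))
  samples <- .poolOverTracks(df, lags, function(m, L) {
    n <- nrow(m)
    if (n < L + 2) return(numeric())
    v <- (m[-1, , drop = FALSE] - m[-n, , drop = FALSE]) / dt
    nv <- nrow(v)
    i <- seq_len(nv - L)
    rowSums(v[i, , drop = FALSE] * v[i + L, , drop = FALSE])
  })
  curve <- .curveFromSamples(lags, samples, "vacf", "frames")
  if (normalize) {
    c0 <- curve@values[curve@lags == 0]
    if (is.finite(c0) && c0 > 0) {
      curve@values <- curve@values / c0
      curve@se <- curve@se / c0
    }
  }
  curve
}

#' 2-d density grid of scattered points
#'
#' Bins the (x, y) cloud into a bins x bins grid spanning the data range,
#' as used for diffusivity-versus-intensity density plots.  A separately
#' smoothed copy (3 x 3 normalized box kernel, edge-truncated) is provided;
#' raw counts are always retained and sum to the number of points.
#'
#' @param x,y coordinates (finite)
#' @param bins grid resolution per axis
#' @return list: \code{counts}, \code{smooth}, \code{xbreaks},
#'   \code{ybreaks}
#' @export
densityGrid <- function(x, y, bins = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("densityGrid: coordinates must be finite")
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0 || diff(ry) == 0) {
    warning("densityGrid: degenerate range; all points in one cell")
    counts <- matrix(length(x), 1, 1)
    return(list(counts = counts, smooth = counts,
                xbreaks = c(rx[1], rx[1]), ybreaks = c(ry[1], ry[1])))
  }
  xb <- seq(rx[1], rx[2], length.out = bins + 1)
  yb <- seq(ry[1], ry[2], length.out = bins + 1)
  xi <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1), bins)
  yi <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1
  # 3x3 normalized box smoothing, truncated at the edges
  sm <- matrix(0, bins, bins)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    ii <- max(1, i - 1):min(bins, i + 1)
    jj <- max(1, j - 1):min(bins, j + 1)
    sm[i, j] <- mean(counts[ii, jj])
  }
  list(counts = counts, smooth = sm, xbreaks = xb, ybreaks = yb)
}

#' Generate synthetic particle tracks with known motion statistics
#'
#' Exact discrete updates (per axis, time step \code{dt}):
#' \describe{
#'   \item{brownian}{x_{k+1} = x_k + sqrt(2 D dt) xi}
#'   \item{confined_ou}{Ornstein-Uhlenbeck in a harmonic trap of stiffness
#'     kappa: x_{k+1} = x_k e^{-kappa dt} + sqrt(D/kappa (1 - e^{-2 kappa
#'     dt})) xi, started from the stationary distribution; the long-time
#'     MSD plateaus at 2 D / kappa per axis}
#'   \item{persistent}{constant drift v along a random fixed direction plus
#'     Brownian noise}
#' }
#'
#' @param model "brownian", "confined_ou" or "persistent"
#' @param nTracks,nPoints number and length of tracks
#' @param dt frame interval
#' @param D diffusivity (position units^2 per time)
#' @param stiffness OU relaxation rate kappa (1/time)
#' @param velocity drift speed for the persistent model
#' @param dim 2 or 3 dimensions
#' @param seed RNG seed
#' @param intensity optional per-track intensity values (recycled)
#' @return a track table
#' @export
simulateTracks <- function(model = c("brownian", "confined_ou", "persistent"),
                           nTracks = 10, nPoints = 100, dt = 1, D = 1,
                           stiffness = 1, velocity = 1, dim = 2, seed = 1,
                           intensity = NULL) {
  model <- match.arg(model)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cols <- c("x", "y", "z")[seq_len(dim)]
  out <- lapply(seq_len(nTracks), function(k) {
    m <- matrix(0, nPoints, dim)
    if (model == "brownian") {
      step <- matrix(rnorm((nPoints - 1) * dim, sd = sqrt(2 * D * dt)),
                     nPoints - 1, dim)
      m[-1, ] <- apply(step, 2, cumsum)
    } else if (model == "confined_ou") {
      a <- exp(-stiffness * dt)
      sdstat <- sqrt(D / stiffness)
      sdstep <- sqrt(D / stiffness * (1 - a^2))
      m[1, ] <- rnorm(dim, sd = sdstat)
      for (i in 2:nPoints) m[i, ] <- m[i - 1, ] * a + rnorm(dim, sd = sdstep)
    } else {
      dir <- rnorm(dim); dir <- dir / sqrt(sum(dir^2))
      drift <- outer((seq_len(nPoints) - 1) * velocity * dt, dir)
      step <- matrix(rnorm((nPoints - 1) * dim, sd = sqrt(2 * D * dt)),
                     nPoints - 1, dim)
      m[-1, ] <- apply(step, 2, cumsum)
      m <- m + drift
    }
    df <- data.frame(track = k, frame = seq_len(nPoints) - 1,
                     t = (seq_len(nPoints) - 1) * dt)
    df[cols] <- m
    if (!is.null(intensity))
      df$intensity <- intensity[(k - 1) %% length(intensity) + 1]
    df
  })
  do.call(rbind, out)
}

#' Select tracks by droplet intensity
#'
#' Keeps tracks whose mean spot intensity is at or below \code{threshold}
#' (or at/below the given \code{quantile} of track intensities), the filter
#' used to compare droplets of similar size across conditions.
#'
#' @param df track table with an \code{intensity} column
#' @param threshold absolute intensity cutoff
#' @param quantile alternative: quantile of per-track mean intensities
#' @return filtered track table with attribute \code{excluded} (number of
#'   tracks removed); a threshold below all intensities returns an empty
#'   table with a warning
#' @export
selectByIntensity <- function(df, threshold = NULL, quantile = NULL) {
  if (is.null(df$intensity)) stop("selectByIntensity: no intensity column")
  m <- tapply(df$intensity, df$track, mean)
  if (is.null(threshold)) {
    if (is.null(quantile)) stop("selectByIntensity: give threshold or quantile")
    threshold <- stats::quantile(m, quantile)
  }
  keep <- names(m)[m <= threshold]
  if (length(keep) == 0)
    warning("selectByIntensity: threshold below all track intensities")
  out <- df[df$track %in% keep, , drop = FALSE]
  attr(out, "excluded") <- length(m) - length(keep)
  out
}

#' Particle tracks from a simulated trajectory
#'
#' Converts stored frames of selected species (by default the inert tracer)
#' into a 3-d track table with unwrapped coordinates, ready for
#' \code{\link{msdCurve}} and \code{\link{estimateDiffusivity}}.
#'
#' @param traj a \linkS4class{SimTrajectory}
#' @param species species name(s) to extract
#' @return track table (track, frame, t, x, y, z), coordinates in nm
#' @export
trajectoryTracks <- function(traj, species = "gem") {
  state <- traj@finalState
  box <- state@composition@box
  idx <- which(particleSpecies(state) %in% species)
  if (length(idx) == 0) stop("trajectoryTracks: no particles of species ",
                             paste(species, collapse = ", "))
  nf <- nFrames(traj)
  out <- lapply(idx, function(i) {
    m <- t(vapply(seq_len(nf), function(f) traj@framePositions[[f]][i, ], numeric(3)))
    m <- .unwrapPath(m, box)
    data.frame(track = i, frame = seq_len(nf) - 1, t = traj@frameTimes,
               x = m[, 1], y = m[, 2], z = m[, 3])
  })
  do.call(rbind, out)
}
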