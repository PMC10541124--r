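# Linking clusters across frames and estimating their diffusivity.

#' Centre of mass of a molecule set, periodic-safe
#'
#' In a periodic box each axis is mapped to a circle and the centre is the
#' circular mean, so a cluster straddling the boundary gets a physically
#' contiguous centre instead of an average of the two images.
#'
#' @param pos N x 3 position matrix of the frame
#' @param members molecule (row) indices of the cluster
#' @param box a \linkS4class{SimulationBox}
#' @return centre-of-mass 3-vector, nm
#' @export
clusterCOM <- function(pos, members, box) {
  stopifnot(length(members) > 0)
  p <- pos[members, , drop = FALSE]
  if (box@boundaryMode != "periodic") return(colMeans(p))
  L <- box@edgeLengths
  vapply(1:3, function(ax) {
    th <- 2 * pi * p[, ax] / L[ax]
    L[ax] / (2 * pi) * atan2(mean(sin(th)), mean(cos(th)))
  }, 0)
}

# best predecessor for each current cluster: most shared members, ties by
# larger overlap fraction then smaller first member id; each predecessor is
# claimed at most once (claim order: larger clusters first)
.matchClusters <- function(prev, cur) {
  link <- rep(NA_integer_, length(cur))
  claimed <- rep(FALSE, length(prev))
  ord <- order(-lengths(cur), vapply(cur, `[`, 0L, 1))
  for (ci in ord) {
    ov <- vapply(seq_along(prev), function(pi) {
      if (claimed[pi]) return(-1L)
      length(intersect(cur[[ci]], prev[[pi]]))
    }, 0L)
    if (!length(ov) || max(ov) <= 0) next
    best <- which(ov == max(ov))
    if (length(best) > 1) {
      frac <- ov[best] / lengths(prev)[best]
      best <- best[frac == max(frac)]
      if (length(best) > 1) {
        firsts <- vapply(prev[best], `[`, 0L, 1)
        best <- best[which.min(firsts)]
      }
    }
    link[ci] <- best[1]
    claimed[best[1]] <- TRUE
  }
  link
}

#' Link clusters across frames into trajectories
#'
#' Clusters larger than \code{minSize} molecules are linked frame-to-frame
#' to the predecessor sharing the largest number of molecules.  A link whose
#' absolute size change reaches \code{splitThreshold} is treated as a
#' different cluster: the track ends and a new one starts (set
#' \code{splitInclusive = FALSE} to split only beyond the threshold).
#'
#' @param partitions per-frame cluster partitions
#'   (\code{\link{trajectoryClusters}})
#' @param positions per-frame N x 3 position matrices
#' @param times frame times
#' @param box a \linkS4class{SimulationBox}
#' @param minSize only clusters with size strictly greater than this enter
#' @param splitThreshold absolute size change that terminates a track
#' @param splitInclusive treat a change equal to the threshold as a split
#' @return list of track data.frames (frame, time, size, x, y, z), each with
#'   attribute \code{members} holding the member set per frame
#' @export
linkClusters <- function(partitions, positions, times, box, minSize = 10,
                         splitThreshold = 20, splitInclusive = TRUE) {
  nf <- length(partitions)
  big <- lapply(partitions, function(p) p[lengths(p) > minSize])
  splits <- function(dsz) if (splitInclusive) dsz >= splitThreshold
                          else dsz > splitThreshold
  # predecessor link per frame transition
  links <- vector("list", nf)
  for (f in seq_len(nf)[-1])
    links[[f]] <- .matchClusters(big[[f - 1]], big[[f]])
  # walk forward assembling chains
  tracks <- list()
  open <- list()   # open[[k]] = list(rows = list of row dfs, members = list)
  prevTrackOf <- integer(0)  # track index per cluster of previous frame
  for (f in seq_len(nf)) {
    cl <- big[[f]]
    trackOf <- integer(length(cl))
    for (ci in seq_along(cl)) {
      com <- clusterCOM(positions[[f]], cl[[ci]], box)
      row <- data.frame(frame = f, time = times[f], size = length(cl[[ci]]),
                        x = com[1], y = com[2], z = com[3])
      pi <- if (f > 1) links[[f]][ci] else NA_integer_
      newTrack <- TRUE
      if (!is.na(pi) && pi <= length(prevTrackOf)) {
        dsz <- abs(length(cl[[ci]]) - length(big[[f - 1]][[pi]]))
        if (!splits(dsz)) {
          k <- prevTrackOf[pi]
          open[[k]]$rows[[length(open[[k]]$rows) + 1]] <- row
          open[[k]]$members[[length(open[[k]]$members) + 1]] <- cl[[ci]]
          trackOf[ci] <- k
          newTrack <- FALSE
        }
      }
      if (newTrack) {
        open[[length(open) + 1]] <- list(rows = list(row),
                                         members = list(cl[[ci]]))
        trackOf[ci] <- length(open)
      }
    }
    prevTrackOf <- trackOf
  }
  lapply(open, function(tr) {
    df <- do.call(rbind, tr$rows)
    attr(df, "members") <- tr$members
    df
  })
}

# time-averaged MSD of an (unwrapped) coordinate matrix for lags 1..maxLag
.timeAveragedMSD <- function(xyz, maxLag) {
  n <- nrow(xyz)
  vapply(seq_len(maxLag), function(L) {
    d <- xyz[seq_len(n - L) + L, , drop = FALSE] -
         xyz[seq_len(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
}

# unwrap a periodic COM series into a continuous path via minimum-image
# displacements between consecutive frames
.unwrapPath <- function(xyz, box) {
  if (box@boundaryMode != "periodic" || nrow(xyz) < 2) return(xyz)
  L <- box@edgeLengths
  d <- diff(xyz)
  for (ax in 1:3) d[, ax] <- d[, ax] - L[ax] * round(d[, ax] / L[ax])
  cum <- apply(d, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  rbind(xyz[1, , drop = FALSE], sweep(cum, 2, xyz[1, ], "+"))
}

#' Diffusivity of a tracked cluster (or particle) from its MSD
#'
#' Computes the time-averaged MSD for lags 1..\code{fitIntervals} and fits
#' a straight line through the origin; in d dimensions the slope is
#' \eqn{2 d D}.  Tracks with 10 or fewer points are rejected (returned with
#' \code{ok = FALSE}).  A curvature diagnostic flags tracks whose MSD is
#' strongly non-linear (e.g. ballistic motion, for which the
#' origin-constrained linear fit is biased).
#'
#' @param xyz n x d coordinate matrix in nm (already unwrapped), or a track
#'   data.frame from \code{\link{linkClusters}}
#' @param dt time per frame
#' @param fitIntervals number of initial lags fitted
#' @param box optional \linkS4class{SimulationBox} used to unwrap a track
#'   data.frame
#' @param minPoints tracks need strictly more than this many points
#' @return list: \code{D} (um^2 per time unit, clipped at 0 with
#'   \code{clipped} flag), \code{Dnm2} (nm^2 per time unit), \code{msd},
#'   \code{curvature} (relative quadratic excess), \code{ok}
#' @export
estimateDiffusivity <- function(xyz, dt = 1, fitIntervals = 10, box = NULL,
                                minPoints = 10) {
  if (is.data.frame(xyz)) {
    m <- as.matrix(xyz[, c("x", "y", "z")])
    if (!is.null(box)) m <- .unwrapPath(m, box)
    xyz <- m
  }
  n <- nrow(xyz)
  if (n <= minPoints)
    return(list(D = NA_real_, Dnm2 = NA_real_, msd = NULL,
                curvature = NA_real_, ok = FALSE, clipped = FALSE))
  d <- ncol(xyz)
  maxLag <- min(fitIntervals, n - 1)
  msd <- .timeAveragedMSD(xyz, maxLag)
  tl <- seq_len(maxLag) * dt
  slope <- sum(msd * tl) / sum(tl^2)          # LS through the origin
  # curvature diagnostic: quadratic term of an unconstrained quadratic fit
  curv <- NA_real_
  if (maxLag >= 3) {
    qf <- lm(msd ~ tl + I(tl^2))
    lin <- abs(coef(qf)[2]) * max(tl)
    quad <- abs(coef(qf)[3]) * max(tl)^2
    curv <- unname(quad / (lin + quad + 1e-300))
  }
  Dnm2 <- slope / (2 * d)
  clipped <- Dnm2 < 0
  if (clipped) Dnm2 <- 0
  list(D = Dnm2 * 1e-6, Dnm2 = Dnm2,
       msd = data.frame(lag = tl, msd = msd),
       curvature = curv, ok = TRUE, clipped = clipped)
}

#' Diffusivity and size of every qualifying cluster track
#'
#' @param tracks output of \code{\link{linkClusters}}
#' @param dt time per frame
#' @param box the \linkS4class{SimulationBox} (for COM unwrapping)
#' @param fitIntervals lags fitted per track
#' @return data.frame: track, size (median over the track), D (um^2/time),
#'   n points; tracks with 10 or fewer points are dropped and counted in
#'   attribute \code{nFiltered}
#' @export
clusterDiffusivities <- function(tracks, dt, box, fitIntervals = 10) {
  rows <- list()
  filtered <- 0
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    est <- estimateDiffusivity(tr, dt = dt, fitIntervals = fitIntervals,
                               box = box)
    if (!est$ok) { filtered <- filtered + 1; next }
    rows[[length(rows) + 1]] <-
      data.frame(track = k, size = median(tr$size), D = est$D,
                 n = nrow(tr))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(track = integer(), size = numeric(), D = numeric(),
                         n = integer())
  attr(out, "nFiltered") <- filtered
  out
}

#' Log-log scaling of cluster diffusivity with cluster size
#'
#' Averages D within each distinct size, then fits log10 D against
#' log10 size by least squares; the slope is the scaling exponent.
#'
#' @param sizes,Ds per-track cluster sizes and diffusivities (positive D
#'   required; zero-D tracks are dropped)
#' @param minSizes minimum number of distinct sizes
#' @return list: \code{slope}, \code{intercept}, \code{n} (distinct sizes)
#' @export
sizeScalingFit <- function(sizes, Ds, minSizes = 5) {
  keep <- is.finite(sizes) & is.finite(Ds) & Ds > 0 & sizes > 0
  sizes <- sizes[keep]; Ds <- Ds[keep]
  mD <- tapply(Ds, sizes, mean)
  sz <- as.numeric(names(mD))
  if (length(sz) < minSizes)
    stop("sizeScalingFit: fewer than ", minSizes, " distinct cluster sizes")
  fit <- lm(log10(as.numeric(mD)) ~ log10(sz))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(sz))
}
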