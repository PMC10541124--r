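# Graph-based cluster identification and size kinetics.
#
# Every synDrop molecule (hexamer or dimer) is a node; a bond between two
# molecules is an edge.  Parallel site-bonds between the same molecule pair
# collapse to a single edge (simple graph).  Crowders and tracers never
# enter the graph.

#' Build the molecular interaction graph of one frame
#'
#' @param bondTable data.frame or matrix whose first and third columns (or
#'   columns \code{molecule_a} / \code{molecule_b}) give the bonded molecule
#'   ids
#' @param roster integer vector of all molecule ids that are graph nodes
#'   (bondable molecules; crowders/tracers are excluded by leaving them out)
#' @return an \code{igraph} simple graph with vertex names equal to the ids
#' @export
buildGraph <- function(bondTable, roster) {
  if (is.matrix(bondTable))
    bondTable <- data.frame(molecule_a = bondTable[, 1],
                            molecule_b = bondTable[, 3])
  a <- bondTable$molecule_a
  b <- bondTable$molecule_b
  if (!all(c(a, b) %in% roster))
    stop("buildGraph: bond list references molecules outside the roster")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(a), to = as.character(b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(roster)))
  igraph::simplify(g)
}

#' Connected clusters of a molecular graph
#'
#' @param g graph from \code{\link{buildGraph}}
#' @return list of integer member-id vectors (each sorted), ordered by
#'   decreasing size with ties broken by smallest member id; the list
#'   partitions the roster, so singletons are included
#' @export
connectedClusters <- function(g) {
  comp <- igraph::components(g)
  ids <- as.integer(igraph::V(g)$name)
  cl <- split(ids, comp$membership)
  cl <- lapply(cl, sort)
  sizes <- lengths(cl)
  firsts <- vapply(cl, `[`, 0L, 1)
  unname(cl[order(-sizes, firsts)])
}

#' Topological distance matrix of a molecular graph
#'
#' Shortest-path length between every molecule pair; pairs in different
#' clusters are unreachable and marked \code{Inf} (rendered as blank pixels
#' in a clustergram).
#'
#' @param g graph from \code{\link{buildGraph}}
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids
#' @export
topologicalDistanceMatrix <- function(g) {
  igraph::distances(g)
}

#' Clustergram ordering of a distance matrix
#'
#' Hierarchical clustering (average linkage) of the topological distance
#' matrix after replacing unreachable entries with a finite sentinel larger
#' than any path length (number of nodes + 1).  Molecules of each connected
#' cluster end up contiguous in the returned order, so the reordered matrix
#' is block-diagonal with one block per cluster.
#'
#' @param d matrix from \code{\link{topologicalDistanceMatrix}}
#' @param sentinel replacement for unreachable distances
#' @return list with \code{order} (permutation of row indices),
#'   \code{labels} (ids in clustergram order), \code{hclust} (the linkage),
#'   and \code{matrix} (the reordered distance matrix, sentinel restored to
#'   \code{Inf})
#' @export
clustergramOrder <- function(d, sentinel = nrow(d) + 1) {
  if (nrow(d) == 1)
    return(list(order = 1L, labels = rownames(d), hclust = NULL, matrix = d))
  ds <- d
  ds[!is.finite(ds)] <- sentinel
  hc <- stats::hclust(stats::as.dist(ds), method = "average")
  ord <- hc$order
  list(order = ord, labels = rownames(d)[ord], hclust = hc,
       matrix = d[ord, ord])
}

#' Cluster-size kinetics over a sequence of frames
#'
#' @param partitions list (one element per frame) of cluster partitions as
#'   returned by \code{\link{connectedClusters}}
#' @param times frame times
#' @param includeSingletons include unbonded molecules as size-1 clusters in
#'   the mean (the default); FALSE averages over clusters of size >= 2 only
#' @return data.frame: time, largest, mean, nClusters
#' @export
sizeKinetics <- function(partitions, times = seq_along(partitions),
                         includeSingletons = TRUE) {
  stopifnot(length(partitions) >= 1)
  rows <- lapply(seq_along(partitions), function(f) {
    sz <- lengths(partitions[[f]])
    use <- if (includeSingletons) sz else sz[sz >= 2]
    data.frame(time = times[f], largest = max(sz),
               mean = if (length(use)) mean(use) else NA_real_,
               nClusters = length(use))
  })
  do.call(rbind, rows)
}

#' Cluster-size histogram of one partition
#'
#' @param partition one element of a partition list
#' @return data.frame: size, count
#' @export
clusterSizeHistogram <- function(partition) {
  tb <- table(lengths(partition))
  data.frame(size = as.integer(names(tb)), count = as.integer(tb))
}

#' Power-law fit of mean cluster size versus time
#'
#' Least squares on log-log within the fit window (by default the initial
#' 0.5 time units of the series, excluding t = 0); the slope is the growth
#' exponent alpha.
#'
#' @param time,size positive numeric vectors
#' @param window two-sided time window \code{c(lo, hi)}
#' @param minPoints minimum points required inside the window
#' @return list: \code{alpha}, \code{prefactor}, \code{residual} (rms of
#'   log residuals), \code{n}
#' @export
fitPowerLaw <- function(time, size, window = c(0, 0.5), minPoints = 5) {
  keep <- is.finite(time) & is.finite(size) & time > 0 &
    time >= window[1] & time <= window[2]
  if (sum(keep) < minPoints)
    stop("fitPowerLaw: fewer than ", minPoints, " points in the fit window")
  if (any(size[keep] <= 0))
    stop("fitPowerLaw: non-positive sizes in the fit window")
  fit <- lm(log(size[keep]) ~ log(time[keep]))
  r <- sqrt(mean(fit$residuals^2))
  list(alpha = unname(coef(fit)[2]), prefactor = exp(unname(coef(fit)[1])),
       residual = r, n = sum(keep))
}

#' Per-frame cluster partitions of a simulation trajectory
#'
#' Collapses each stored frame's bond edge list to the molecule graph
#' (bondable species only) and returns its connected clusters.
#'
#' @param traj a \linkS4class{SimTrajectory}
#' @return list of partitions, one per frame
#' @export
trajectoryClusters <- function(traj) {
  state <- traj@finalState
  comp <- state@composition
  bondable <- vapply(comp@species, function(s) valence(s) > 0, TRUE)
  roster <- which(bondable[state@speciesIndex])
  lapply(traj@frameBonds, function(b) {
    g <- buildGraph(data.frame(molecule_a = b[, 1], molecule_b = b[, 3]),
                    roster)
    connectedClusters(g)
  })
}
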