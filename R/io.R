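# Plain-text trajectory output: extended-XYZ frames and bond edge lists.

#' Write trajectory frames as extended XYZ
#'
#' One block per stored frame: atom count, a comment line carrying the
#' frame time and box (Lattice= convention), then one line per particle
#' with the species label and position in nm.
#'
#' @param traj a \linkS4class{SimTrajectory}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  state <- traj@finalState
  lab <- particleSpecies(state)
  box <- state@composition@box@edgeLengths
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    p <- traj@framePositions[[f]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
      box[1], box[2], box[3], traj@frameTimes[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Write per-frame bond edge lists as CSV
#'
#' Columns: frame, time, molecule_a, site_a, molecule_b, site_b - the
#' format consumed by the cluster-graph module.
#'
#' @param traj a \linkS4class{SimTrajectory}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeBondEdgeCSV <- function(traj, path) {
  rows <- lapply(seq_len(nFrames(traj)), function(f) {
    b <- traj@frameBonds[[f]]
    if (nrow(b) == 0) return(NULL)
    data.frame(frame = f, time = traj@frameTimes[f], molecule_a = b[, 1],
               site_a = b[, 2], molecule_b = b[, 3], site_b = b[, 4])
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(frame = integer(), time = numeric(),
                     molecule_a = integer(), site_a = integer(),
                     molecule_b = integer(), site_b = integer())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a bond edge-list CSV
#'
#' @param path file from \code{\link{writeBondEdgeCSV}}
#' @return data.frame with one row per bond per frame
#' @export
readBondEdgeCSV <- function(path) read.csv(path)

#' Write bond events as CSV
#'
#' @param traj a \linkS4class{SimTrajectory} recorded with
#'   \code{logEvents = TRUE}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeBondEventCSV <- function(traj, path) {
  ev <- as.data.frame(traj@events)
  ev$time <- ev$step * traj@dt
  ev$event <- ifelse(ev$event == 1, "form", "break")
  write.csv(ev[, c("time", "event", "molecule_a", "site_a", "molecule_b",
                   "site_b")], path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame cluster tables as CSV
#'
#' @param partitions per-frame cluster partitions
#' @param positions per-frame position matrices
#' @param times frame times
#' @param box the \linkS4class{SimulationBox}
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeClusterTableCSV <- function(partitions, positions, times, box, path) {
  rows <- list()
  for (f in seq_along(partitions)) {
    for (ci in seq_along(partitions[[f]])) {
      mem <- partitions[[f]][[ci]]
      com <- clusterCOM(positions[[f]], mem, box)
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, time = times[f], cluster = ci, size = length(mem),
        x = com[1], y = com[2], z = com[3])
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
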