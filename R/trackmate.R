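# TrackMate-dialect XML ingestion and emission.
#
# Only the exported spot/track model is parsed: spots with positions,
# frames and intensities under AllSpots, and tracks as edge lists under
# AllTracks.  Spot detection itself is upstream (TrackMate's job).

#' Read particle tracks from a TrackMate XML export
#'
#' Reconstructs tracks from the spot table and the per-track edge lists.
#' Gap-closing edges (frame jumps greater than one) are preserved as frame
#' gaps in the output, so lag statistics computed on the result
#' automatically skip bridged intervals.  If the model carries no spatial
#' unit metadata a warning states the assumption that positions are in the
#' stored units.
#'
#' @param path XML file path
#' @return track table (track, frame, t, x, y, z, intensity) with attribute
#'   \code{spatialUnits}
#' @export
readTrackMateXML <- function(path) {
  doc <- xml2::read_xml(path)
  model <- xml2::xml_find_first(doc, ".//Model")
  if (inherits(model, "xml_missing"))
    stop("readTrackMateXML: no <Model> element; not a TrackMate export")
  units <- xml2::xml_attr(model, "spatialunits")
  if (is.na(units)) {
    warning("readTrackMateXML: no spatial unit metadata; assuming ",
            "positions are in image units")
    units <- "unknown"
  }
  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (length(spots) == 0) stop("readTrackMateXML: no spots found")
  num <- function(attr) as.numeric(xml2::xml_attr(spots, attr))
  stab <- data.frame(
    id = as.integer(xml2::xml_attr(spots, "ID")),
    frame = as.integer(num("FRAME")),
    t = num("POSITION_T"),
    x = num("POSITION_X"), y = num("POSITION_Y"), z = num("POSITION_Z"),
    intensity = num("MEAN_INTENSITY_CH1"))
  tracks <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  out <- lapply(tracks, function(tk) {
    tid <- as.integer(xml2::xml_attr(tk, "TRACK_ID"))
    edges <- xml2::xml_find_all(tk, ".//Edge")
    ids <- unique(c(
      as.integer(xml2::xml_attr(edges, "SPOT_SOURCE_ID")),
      as.integer(xml2::xml_attr(edges, "SPOT_TARGET_ID"))))
    rows <- stab[match(ids, stab$id), , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    data.frame(track = tid, rows[, c("frame", "t", "x", "y", "z",
                                     "intensity")])
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "spatialUnits") <- units
  df
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a track table as TrackMate-dialect XML
#'
#' Emits the spot/track model consumed by \code{\link{readTrackMateXML}};
#' writing and re-reading a table reproduces it exactly.  Used to build
#' round-trip fixtures and to hand simulated tracks to TrackMate-aware
#' tools.
#'
#' @param df track table (track, frame, t, x, y[, z, intensity])
#' @param path output file
#' @param spatialUnits value for the model's unit attribute
#' @return invisibly, \code{path}
#' @export
writeTrackMateXML <- function(df, path, spatialUnits = "micron") {
  if (is.null(df$z)) df$z <- 0
  if (is.null(df$intensity)) df$intensity <- 0
  df$.spot <- seq_len(nrow(df)) - 1L
  doc <- xml2::xml_new_root("TrackMate", version = "7.0")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = spatialUnits,
                               timeunits = "s")
  allspots <- xml2::xml_add_child(model, "AllSpots",
                                  nspots = as.character(nrow(df)))
  for (fr in sort(unique(df$frame))) {
    sf <- xml2::xml_add_child(allspots, "SpotsInFrame",
                              frame = as.character(fr))
    rows <- df[df$frame == fr, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      xml2::xml_add_child(sf, "Spot",
        ID = as.character(rows$.spot[i]),
        name = paste0("ID", rows$.spot[i]),
        FRAME = as.character(rows$frame[i]),
        POSITION_T = .fmt(rows$t[i]),
        POSITION_X = .fmt(rows$x[i]),
        POSITION_Y = .fmt(rows$y[i]),
        POSITION_Z = .fmt(rows$z[i]),
        MEAN_INTENSITY_CH1 = .fmt(rows$intensity[i]))
  }
  alltracks <- xml2::xml_add_child(model, "AllTracks")
  ftracks <- xml2::xml_add_child(model, "FilteredTracks")
  for (tid in unique(df$track)) {
    rows <- df[df$track == tid, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    tk <- xml2::xml_add_child(alltracks, "Track",
                              TRACK_ID = as.character(tid),
                              name = paste0("Track_", tid))
    if (nrow(rows) > 1)
      for (i in seq_len(nrow(rows) - 1))
        xml2::xml_add_child(tk, "Edge",
          SPOT_SOURCE_ID = as.character(rows$.spot[i]),
          SPOT_TARGET_ID = as.character(rows$.spot[i + 1]))
    xml2::xml_add_child(ftracks, "TrackID", TRACK_ID = as.character(tid))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
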