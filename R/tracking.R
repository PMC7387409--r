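# Detection-to-track linking, track-length exclusion, region assignment.

#' Link per-frame detections into tracks
#'
#' Deterministic greedy nearest-neighbour linking: frame by frame, candidate
#' (track, detection) pairs within the gating distance are assigned in order
#' of increasing distance, with ties broken by lower cell id then lower
#' detection index. Tracks missing from up to \code{maxGap} consecutive
#' frames can be bridged; detections that cannot be linked start new tracks,
#' so every detection appears in exactly one (possibly length-1) track.
#'
#' @param detections data.frame (frame, x_um, y_um, ...) sorted by frame,
#'   as from \code{\link{detectSpots}}.
#' @param maxStepUm gating distance: no link may be longer than this.
#' @param maxGap maximum number of bridged missing frames.
#' @param frameInterval minutes per frame, for track times.
#' @param mouse,arm metadata attached to the returned set.
#' @return a \code{\linkS4class{TrackSet}}.
#' @export
linkDetections <- function(detections, maxStepUm = 10, maxGap = 1L,
                           frameInterval = 0.5, mouse = NA_character_,
                           arm = NA_character_) {
  stopIfNot(all(c("frame", "x_um", "y_um") %in% names(detections)),
            "detections need columns frame, x_um, y_um")
  if (!nrow(detections))
    return(TrackSet(list(), mouse = mouse, arm = arm))
  stopIfNot(!is.unsorted(detections$frame), "detections must be frame-sorted")

  # open tracks: list of (id, lastFrame, lastX, lastY, rows)
  open <- list()
  done <- list()
  nextId <- 1L
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    # retire tracks too old to bridge
    if (length(open)) {
      ages <- vapply(open, function(o) f - o$lastFrame, numeric(1L))
      retire <- ages > maxGap + 1L
      done <- c(done, open[retire])
      open <- open[!retire]
    }
    assignedDet <- rep(FALSE, nrow(det))
    if (length(open) && nrow(det)) {
      cand <- expand.grid(ti = seq_along(open), di = seq_len(nrow(det)))
      cand$dist <- sqrt(
        (vapply(open, `[[`, numeric(1L), "lastX")[cand$ti] - det$x_um[cand$di])^2 +
        (vapply(open, `[[`, numeric(1L), "lastY")[cand$ti] - det$y_um[cand$di])^2)
      cand <- cand[cand$dist <= maxStepUm, , drop = FALSE]
      ids <- vapply(open, `[[`, character(1L), "id")
      cand <- cand[order(cand$dist, ids[cand$ti], cand$di), , drop = FALSE]
      usedTrack <- rep(FALSE, length(open))
      for (k in seq_len(nrow(cand))) {
        ti <- cand$ti[k]; di <- cand$di[k]
        if (usedTrack[ti] || assignedDet[di]) next
        usedTrack[ti] <- TRUE; assignedDet[di] <- TRUE
        open[[ti]]$rows <- rbind(open[[ti]]$rows,
                                 c(f, det$x_um[di], det$y_um[di]))
        open[[ti]]$lastFrame <- f
        open[[ti]]$lastX <- det$x_um[di]; open[[ti]]$lastY <- det$y_um[di]
      }
    }
    for (di in which(!assignedDet)) {
      open[[length(open) + 1L]] <- list(
        id = sprintf("cell_%04d", nextId), lastFrame = f,
        lastX = det$x_um[di], lastY = det$y_um[di],
        rows = matrix(c(f, det$x_um[di], det$y_um[di]), 1L))
      nextId <- nextId + 1L
    }
  }
  done <- c(done, open)
  ids <- vapply(done, `[[`, character(1L), "id")
  done <- done[order(ids)]
  trs <- lapply(done, function(o) {
    Track(id = o$id, frame = o$rows[, 1L], x = o$rows[, 2L],
          y = o$rows[, 3L], frameInterval = frameInterval)
  })
  TrackSet(trs, mouse = mouse, arm = arm)
}

#' Exclude tracks observed for too few timepoints
#'
#' Retains exactly the tracks with strictly more than \code{minTimepoints}
#' observations: with the default of 5, a 5-point track is removed and a
#' 6-point track retained. Idempotent.
#'
#' @param trackSet a \code{\linkS4class{TrackSet}}.
#' @param minTimepoints exclusion threshold (>= 2); tracks must exceed it.
#' @return the filtered \code{TrackSet}.
#' @export
filterShortTracks <- function(trackSet, minTimepoints = 5L) {
  stopIfNot(is(trackSet, "TrackSet"), "trackSet must be a TrackSet")
  stopIfNot(minTimepoints >= 2, "minTimepoints must be >= 2")
  keep <- vapply(tracks(trackSet),
                 function(t) nFrames(t) > minTimepoints, logical(1L))
  out <- trackSet
  out@tracks <- trackSet@tracks[keep]
  out
}

#' Assign peritumoral/intratumoral region labels to tracks
#'
#' Each track gets the label of the compartment containing the majority of
#' its positions; ties go to peritumoral (conservative toward the collagen
#' interface). Tracks entirely outside both masks stay unassigned.
#'
#' @param trackSet a \code{\linkS4class{TrackSet}}.
#' @param periphery,core disjoint logical (height x width) masks that
#'   together tile the field, e.g. from \code{\link{peripheryMask}}.
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @return the \code{TrackSet} with region slots filled.
#' @export
assignRegion <- function(trackSet, periphery, core, pixelSize = 1) {
  stopIfNot(is(trackSet, "TrackSet"), "trackSet must be a TrackSet")
  stopIfNot(!any(periphery & core), "masks must be disjoint")
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  h <- nrow(periphery); w <- ncol(periphery)
  out <- trackSet
  out@tracks <- lapply(tracks(trackSet), function(tr) {
    col <- floor(tr@x / pixelSize[1L]) + 1L
    row <- floor(tr@y / pixelSize[2L]) + 1L
    inside <- col >= 1L & col <= w & row >= 1L & row <= h
    nPeri <- sum(periphery[cbind(row[inside], col[inside])])
    nCore <- sum(core[cbind(row[inside], col[inside])])
    tr@region <- if (nPeri + nCore == 0L) "unassigned"
                 else if (nPeri >= nCore) "peritumoral"
                 else "intratumoral"
    tr
  })
  out
}
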