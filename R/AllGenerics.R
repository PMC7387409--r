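#' Number of frames
#' @param x a stack, projected series or track container.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame interval in minutes
#' @param x a calibrated object.
#' @return minutes per frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Channel labels
#' @param x a multi-channel object.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' In-plane pixel calibration
#' @param x a calibrated object.
#' @return um per pixel, (x, y).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Track coordinates as a data.frame
#' @param x a \code{Track} or \code{TrackSet}.
#' @return data.frame with columns cell_id, frame, t_min, x_um, y_um, region.
#' @export
setGeneric("trackCoords", function(x) standardGeneric("trackCoords"))

#' Tracks contained in a set
#' @param x a \code{TrackSet}.
#' @return list of \code{Track} objects.
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' Number of tracks
#' @param x a \code{TrackSet}.
#' @return integer count.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' Region label(s)
#' @param x a \code{Track} or \code{TrackSet}.
#' @return character region label(s).
#' @export
setGeneric("region", function(x) standardGeneric("region"))

#' Elongation index of a segmented contour
#'
#' Ratio of the fitted-ellipse major to minor axis (>= 1); 1 is a round
#' cell, larger values indicate an elongated, lamellipodial shape.
#' @param x a \code{ContourMask}.
#' @return numeric elongation index.
#' @export
setGeneric("elongationIndex", function(x) standardGeneric("elongationIndex"))

# -- accessors ---------------------------------------------------------------

#' @rdname nFrames
setMethod("nFrames", "TimeLapseStack", function(x) dim(x@voxels)[1L])
#' @rdname nFrames
setMethod("nFrames", "ProjectedSeries", function(x) dim(x@frames)[1L])
#' @rdname nFrames
setMethod("nFrames", "Track", function(x) length(x@frame))

#' @rdname frameInterval
setMethod("frameInterval", "TimeLapseStack", function(x) x@frameInterval)
#' @rdname frameInterval
setMethod("frameInterval", "ProjectedSeries", function(x) x@frameInterval)
#' @rdname frameInterval
setMethod("frameInterval", "SceneGeometry", function(x) x@frameInterval)

#' @rdname channelNames
setMethod("channelNames", "TimeLapseStack", function(x) x@channels)
#' @rdname channelNames
setMethod("channelNames", "ProjectedSeries", function(x) x@channels)

#' @rdname pixelSize
setMethod("pixelSize", "TimeLapseStack", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "ProjectedSeries", function(x) x@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "SceneGeometry", function(x) x@pixelSize)

#' @rdname tracks
setMethod("tracks", "TrackSet", function(x) x@tracks)
#' @rdname nTracks
setMethod("nTracks", "TrackSet", function(x) length(x@tracks))

#' @rdname region
setMethod("region", "Track", function(x) x@region)
#' @rdname region
setMethod("region", "TrackSet",
          function(x) vapply(x@tracks, function(t) t@region, character(1L)))

#' @rdname trackCoords
setMethod("trackCoords", "Track", function(x) {
  data.frame(cell_id = x@id, frame = x@frame, t_min = x@time,
             x_um = x@x, y_um = x@y, region = x@region,
             stringsAsFactors = FALSE)
})

#' @rdname trackCoords
setMethod("trackCoords", "TrackSet", function(x) {
  if (length(x@tracks) == 0L)
    return(data.frame(cell_id = character(), frame = integer(),
                      t_min = numeric(), x_um = numeric(),
                      y_um = numeric(), region = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(lapply(x@tracks, trackCoords),
                   list(make.row.names = FALSE)))
})

#' @rdname elongationIndex
setMethod("elongationIndex", "ContourMask",
          function(x) x@majorUm / x@minorUm)

# -- show methods ------------------------------------------------------------

setMethod("show", "MotionModel", function(object) {
  cat(sprintf("MotionModel: %s (speed %.3g um/min, persistence %.2f)\n",
              object@kind, object@speedScale, object@persistence))
  if (object@kind == "levy")
    cat(sprintf("  levy exponent %.3g, truncation %.3g um\n",
                object@levyExponent, object@truncationStep))
  if (object@kind == "confined_brownian")
    cat(sprintf("  confinement radius %.3g um\n", object@confinementRadius))
  invisible(NULL)
})

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(paste0("TimeLapseStack: %d frames x %d z x %d channels ",
                     "(%d x %d px)\n"), d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  channels: %s\n", paste(object@channels, collapse = ", ")))
  cat(sprintf("  %.3g x %.3g um/px, %.3g um/slice, %.3g min/frame\n",
              object@pixelSize[1], object@pixelSize[2], object@sliceDepth,
              object@frameInterval))
  invisible(NULL)
})

setMethod("show", "ProjectedSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ProjectedSeries: %d frames x %d channels (%d x %d px)\n",
              d[1], d[2], d[3], d[4]))
  invisible(NULL)
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s': %d points, %.3g min, region %s\n", object@id,
              length(object@frame), diff(range(object@time)), object@region))
  invisible(NULL)
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d tracks (mouse %s, arm %s)\n",
              length(object@tracks), object@mouse, object@arm))
  tab <- table(factor(region(object), levels = REGION_LEVELS))
  cat(sprintf("  regions: %s\n",
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "ClassifierThresholds", function(object) {
  cat(sprintf("ClassifierThresholds: v* = %.4g um/min, MI* = %.4g\n",
              object@vStar, object@miStar))
  invisible(NULL)
})

setMethod("show", "SpatialHistogram", function(object) {
  cat(sprintf(paste0("SpatialHistogram: %d cells in %d bins; ",
                     "Pearson kurtosis %.4g (excess %.4g)\n"),
              object@nCells, length(object@counts), object@kurtosis,
              object@excessKurtosis))
  invisible(NULL)
})

setMethod("show", "StatResult", function(object) {
  cat(sprintf("StatResult: %s (%s)\n", object@test,
              paste(object@groups, collapse = " vs ")))
  cat(sprintf("  statistic = %.6g, p = %.4g\n", object@statistic, object@p))
  if (nzchar(object@gate)) cat(" ", object@gate, "\n")
  if (nrow(object@posthoc)) {
    cat("  post-hoc:\n")
    print(object@posthoc, row.names = FALSE)
  }
  invisible(NULL)
})
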