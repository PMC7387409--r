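#' @import methods
NULL

MOTION_KINDS <- c("ballistic", "confined_brownian", "levy", "stationary_probing")
REGION_LEVELS <- c("peritumoral", "intratumoral", "unassigned")

#' Motion model for synthetic T-cell trajectories
#'
#' Parameterises one of four migratory regimes observed intravitally:
#' ballistic (persistent directional crawling along collagen fibers),
#' confined Brownian motion (cells trapped near a target), truncated
#' Levy walks (clusters of small steps interspersed with long relocations),
#' and stationary probing (near-zero displacement with membrane jitter).
#'
#' @slot kind one of \code{"ballistic"}, \code{"confined_brownian"},
#'   \code{"levy"}, \code{"stationary_probing"}.
#' @slot speedScale characteristic speed in micrometres per minute; the mean
#'   per-frame step length is \code{speedScale * dt}.
#' @slot persistence directional persistence in \code{[0, 1]}; 0 is isotropic
#'   re-orientation each frame, 1 is a fixed heading.
#' @slot levyExponent power-law exponent (> 1) of the step-length tail
#'   (Levy only).
#' @slot confinementRadius hard confinement radius in micrometres
#'   (confined Brownian only).
#' @slot truncationStep maximum step length in micrometres (Levy only).
#' @export
setClass("MotionModel",
  representation(
    kind = "character",
    speedScale = "numeric",
    persistence = "numeric",
    levyExponent = "numeric",
    confinementRadius = "numeric",
    truncationStep = "numeric"
  ),
  prototype(
    persistence = 0, levyExponent = 2, confinementRadius = 10,
    truncationStep = 25
  )
)

setValidity("MotionModel", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% MOTION_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(MOTION_KINDS, collapse = ", ")))
  pars <- c(object@speedScale, object@persistence, object@levyExponent,
            object@confinementRadius, object@truncationStep)
  if (any(!is.finite(pars)))
    return(c(msg, "all motion parameters must be finite"))
  if (length(object@speedScale) != 1L || object@speedScale < 0)
    msg <- c(msg, "speedScale must be a single non-negative number")
  if (object@persistence < 0 || object@persistence > 1)
    msg <- c(msg, "persistence must lie in [0, 1]")
  if (object@levyExponent <= 1)
    msg <- c(msg, "levyExponent must be > 1")
  if (object@confinementRadius <= 0)
    msg <- c(msg, "confinementRadius must be > 0")
  if (object@truncationStep <= 0)
    msg <- c(msg, "truncationStep must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MotionModel
#'
#' @param kind motility regime; see \code{\linkS4class{MotionModel}}.
#' @param speedScale characteristic speed (um/min).
#' @param persistence directional persistence in \code{[0, 1]}.
#' @param levyExponent step-length power-law exponent (> 1; Levy only).
#' @param confinementRadius confinement radius in um (confined only).
#' @param truncationStep maximum Levy step in um.
#' @return a \code{MotionModel} object.
#' @examples
#' MotionModel("ballistic", speedScale = 5)
#' @export
MotionModel <- function(kind, speedScale, persistence = 0,
                        levyExponent = 2, confinementRadius = 10,
                        truncationStep = 25) {
  new("MotionModel", kind = kind, speedScale = speedScale,
      persistence = persistence, levyExponent = levyExponent,
      confinementRadius = confinementRadius, truncationStep = truncationStep)
}

#' Scene geometry for the two-compartment tumor field
#'
#' Describes the imaged field: its pixel dimensions, physical calibration,
#' and the split into a collagen-rich peritumoral band along the low-x edge
#' and the complementary tumor core. Increasing x points from the stromal
#' periphery toward the tumor core throughout the package.
#'
#' @slot fieldSize integer (height, width) in pixels.
#' @slot pixelSize um per pixel, (x, y).
#' @slot sliceDepth um per z-slice.
#' @slot frameInterval minutes per frame.
#' @slot peripheryWidthPx width in pixels of the peritumoral band occupying
#'   columns \code{[0, peripheryWidthPx)} (0-based, half-open).
#' @export
setClass("SceneGeometry",
  representation(
    fieldSize = "integer",
    pixelSize = "numeric",
    sliceDepth = "numeric",
    frameInterval = "numeric",
    peripheryWidthPx = "integer"
  )
)

setValidity("SceneGeometry", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 1L))
    msg <- c(msg, "fieldSize must be two positive integers (height, width)")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be two positive numbers (x, y)")
  if (object@sliceDepth <= 0) msg <- c(msg, "sliceDepth must be > 0")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@peripheryWidthPx < 0L ||
      object@peripheryWidthPx > object@fieldSize[2L])
    msg <- c(msg, "peripheryWidthPx must lie within [0, field width]")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneGeometry
#'
#' Defaults mirror a typical intravital acquisition: 30-s frame interval and
#' 5-um z-steps.
#'
#' @param fieldSize (height, width) in pixels.
#' @param pixelSize um/pixel; a scalar is used for both x and y.
#' @param sliceDepth um per z-slice.
#' @param frameInterval minutes per frame.
#' @param peripheryWidthPx width of the peritumoral band (pixels, low-x edge).
#' @return a \code{SceneGeometry}.
#' @export
SceneGeometry <- function(fieldSize = c(256L, 256L), pixelSize = 1,
                          sliceDepth = 5, frameInterval = 0.5,
                          peripheryWidthPx = round(fieldSize[2] / 4)) {
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  new("SceneGeometry", fieldSize = as.integer(fieldSize),
      pixelSize = pixelSize, sliceDepth = sliceDepth,
      frameInterval = frameInterval,
      peripheryWidthPx = as.integer(peripheryWidthPx))
}

#' Cohort specification for synthetic study arms
#'
#' Describes a multi-arm cohort (e.g. vehicle control, checkpoint-inhibitor
#' monotherapy, combination therapy): per arm the number of mice, cells per
#' mouse, a mixture over motion models, and a speed multiplier applied to
#' every model's \code{speedScale} so treated arms can be made slower.
#'
#' @slot arms a list; each element is a list with entries \code{label},
#'   \code{nMice}, \code{cellsPerMouse}, \code{models} (list of
#'   \code{MotionModel}), \code{weights} (mixture weights summing to 1) and
#'   \code{speedMultiplier}.
#' @slot seed integer master seed.
#' @export
setClass("CohortSpec", representation(arms = "list", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@arms) < 1L) msg <- c(msg, "at least one arm is required")
  for (arm in object@arms) {
    need <- c("label", "nMice", "cellsPerMouse", "models", "weights",
              "speedMultiplier")
    if (!all(need %in% names(arm))) {
      msg <- c(msg, sprintf("arm is missing fields: %s",
                            paste(setdiff(need, names(arm)), collapse = ", ")))
      next
    }
    if (arm$nMice < 1L || arm$cellsPerMouse < 1L)
      msg <- c(msg, sprintf("arm '%s': counts must be >= 1", arm$label))
    if (length(arm$models) != length(arm$weights))
      msg <- c(msg, sprintf("arm '%s': one weight per model", arm$label))
    if (abs(sum(arm$weights) - 1) > 1e-8)
      msg <- c(msg, sprintf("arm '%s': mixture weights must sum to 1",
                            arm$label))
    if (!all(vapply(arm$models, is, logical(1L), "MotionModel")))
      msg <- c(msg, sprintf("arm '%s': models must be MotionModel objects",
                            arm$label))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param arms list of arm definitions (see \code{\linkS4class{CohortSpec}}).
#' @param seed master seed; fanned out deterministically to per-mouse and
#'   per-cell sub-seeds.
#' @return a \code{CohortSpec}.
#' @export
CohortSpec <- function(arms, seed = 1L) {
  new("CohortSpec", arms = arms, seed = as.integer(seed))
}

#' Calibrated multi-channel time-lapse stack
#'
#' Voxel container for a 3D+t multi-channel acquisition, indexed
#' (t, z, channel, y, x), with the physical calibration needed to convert
#' pixel positions into micrometres and frame indices into minutes.
#'
#' @slot voxels 5-d numeric array (t, z, channel, y, x), non-negative.
#' @slot pixelSize um/pixel (x, y).
#' @slot sliceDepth um per z-slice.
#' @slot frameInterval minutes per frame.
#' @slot channels channel labels, one per channel plane.
#' @export
setClass("TimeLapseStack",
  representation(
    voxels = "array",
    pixelSize = "numeric",
    sliceDepth = "numeric",
    frameInterval = "numeric",
    channels = "character"
  )
)

setValidity("TimeLapseStack", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 5L) msg <- c(msg, "voxels must be a 5-d array (t,z,c,y,x)")
  else {
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    if (length(object@channels) != d[3L])
      msg <- c(msg, "one channel label per channel plane")
  }
  if (any(object@voxels < 0)) msg <- c(msg, "intensities must be non-negative")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0) ||
      object@sliceDepth <= 0 || object@frameInterval <= 0)
    msg <- c(msg, "calibration must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeLapseStack
#' @param voxels 5-d array (t, z, channel, y, x).
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @param sliceDepth um per z-slice.
#' @param frameInterval minutes per frame.
#' @param channels channel labels.
#' @return a \code{TimeLapseStack}.
#' @export
TimeLapseStack <- function(voxels, pixelSize = 1, sliceDepth = 5,
                           frameInterval = 0.5,
                           channels = paste0("ch", seq_len(dim(voxels)[3]))) {
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  new("TimeLapseStack", voxels = voxels, pixelSize = pixelSize,
      sliceDepth = sliceDepth, frameInterval = frameInterval,
      channels = channels)
}

#' Maximum-intensity projected series
#'
#' A z-projected time-lapse: frames indexed (t, channel, y, x) carrying the
#' in-plane and temporal calibration of the parent stack.
#'
#' @slot frames 4-d numeric array (t, channel, y, x).
#' @slot pixelSize um/pixel (x, y).
#' @slot frameInterval minutes per frame.
#' @slot channels channel labels.
#' @export
setClass("ProjectedSeries",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    channels = "character"
  )
)

setValidity("ProjectedSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 4L) msg <- c(msg, "frames must be a 4-d array (t,c,y,x)")
  else if (length(object@channels) != d[2L])
    msg <- c(msg, "one channel label per channel plane")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0) ||
      object@frameInterval <= 0)
    msg <- c(msg, "calibration must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ProjectedSeries
#' @param frames 4-d array (t, channel, y, x).
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @param frameInterval minutes per frame.
#' @param channels channel labels.
#' @return a \code{ProjectedSeries}.
#' @export
ProjectedSeries <- function(frames, pixelSize = 1, frameInterval = 0.5,
                            channels = paste0("ch", seq_len(dim(frames)[2]))) {
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  new("ProjectedSeries", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval, channels = channels)
}

#' Single-cell trajectory
#'
#' An ordered sequence of centroid positions for one tracked cell, in
#' physical units, with an optional tumor-compartment label. Length-1 tracks
#' may arise transiently during linking and are removed by
#' \code{\link{filterShortTracks}}; all motility metrics require at least two
#' points.
#'
#' @slot id cell identifier, unique within a \code{TrackSet}.
#' @slot frame integer frame indices, strictly increasing (1-based).
#' @slot time acquisition times in minutes, \code{(frame - 1) * frameInterval}.
#' @slot x,y centroid coordinates in micrometres.
#' @slot region \code{"peritumoral"}, \code{"intratumoral"} or
#'   \code{"unassigned"}.
#' @export
setClass("Track",
  representation(
    id = "character", frame = "integer", time = "numeric",
    x = "numeric", y = "numeric", region = "character"
  ),
  prototype(region = "unassigned")
)

setValidity("Track", function(object) {
  msg <- character()
  n <- length(object@frame)
  if (n < 1L) msg <- c(msg, "a track needs at least one point")
  if (length(object@time) != n || length(object@x) != n ||
      length(object@y) != n)
    msg <- c(msg, "frame, time, x and y must have equal length")
  if (n > 1L && any(diff(object@frame) <= 0L))
    msg <- c(msg, "frame indices must be strictly increasing")
  if (!object@region %in% REGION_LEVELS)
    msg <- c(msg, "region must be peritumoral, intratumoral or unassigned")
  if (any(!is.finite(c(object@x, object@y, object@time))))
    msg <- c(msg, "coordinates and times must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Track
#' @param id cell identifier.
#' @param frame 1-based frame indices.
#' @param x,y positions in um.
#' @param frameInterval minutes per frame (used to derive times).
#' @param time acquisition times in minutes; derived from \code{frame} when
#'   omitted.
#' @param region compartment label.
#' @return a \code{Track}.
#' @export
Track <- function(id, frame, x, y, frameInterval = 0.5,
                  time = (frame - 1) * frameInterval,
                  region = "unassigned") {
  new("Track", id = as.character(id), frame = as.integer(frame),
      time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
      region = region)
}

#' A set of tracks from one imaging session
#'
#' @slot tracks list of \code{\linkS4class{Track}} with unique ids.
#' @slot mouse,arm,imagingRegion source metadata.
#' @export
setClass("TrackSet",
  representation(
    tracks = "list", mouse = "character", arm = "character",
    imagingRegion = "character"
  ),
  prototype(mouse = NA_character_, arm = NA_character_,
            imagingRegion = NA_character_)
)

setValidity("TrackSet", function(object) {
  if (!all(vapply(object@tracks, is, logical(1L), "Track")))
    return("all elements must be Track objects")
  ids <- vapply(object@tracks, function(t) t@id, character(1L))
  if (anyDuplicated(ids)) return("cell ids must be unique within a TrackSet")
  TRUE
})

#' Construct a TrackSet
#' @param tracks list of \code{Track} objects.
#' @param mouse,arm,imagingRegion source metadata.
#' @return a \code{TrackSet}.
#' @export
TrackSet <- function(tracks, mouse = NA_character_, arm = NA_character_,
                     imagingRegion = NA_character_) {
  new("TrackSet", tracks = tracks, mouse = mouse, arm = arm,
      imagingRegion = imagingRegion)
}

#' Segmented cell contour with fitted-ellipse axes
#'
#' @slot frame frame index.
#' @slot cellId detection/cell identifier.
#' @slot mask logical matrix (window rows = y, cols = x) containing one
#'   connected component.
#' @slot offset 0-based (x, y) pixel offset of the window within the field.
#' @slot majorUm,minorUm full fitted-ellipse axes in um (major >= minor > 0),
#'   from second-order region moments.
#' @export
setClass("ContourMask",
  representation(
    frame = "integer", cellId = "character", mask = "matrix",
    offset = "integer", majorUm = "numeric", minorUm = "numeric"
  )
)

setValidity("ContourMask", function(object) {
  msg <- character()
  if (!(object@majorUm >= object@minorUm && object@minorUm > 0))
    msg <- c(msg, "axes must satisfy major >= minor > 0")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' Behavioral classifier thresholds
#'
#' The velocity and meandering-index cut points used to divide the
#' velocity-vs-straightness plane into four behavioral quadrants. The
#' published analysis used the cohort-wide means of both quantities
#' (2.16 um/min and 0.45).
#'
#' @slot vStar velocity threshold, um/min (> 0).
#' @slot miStar meandering-index threshold in (0, 1).
#' @export
setClass("ClassifierThresholds",
         representation(vStar = "numeric", miStar = "numeric"))

setValidity("ClassifierThresholds", function(object) {
  msg <- character()
  if (!(is.finite(object@vStar) && object@vStar > 0))
    msg <- c(msg, "vStar must be > 0")
  if (!(is.finite(object@miStar) && object@miStar > 0 && object@miStar < 1))
    msg <- c(msg, "miStar must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param vStar velocity threshold (um/min).
#' @param miStar meandering-index threshold.
#' @rdname ClassifierThresholds-class
#' @export
ClassifierThresholds <- function(vStar, miStar) {
  new("ClassifierThresholds", vStar = vStar, miStar = miStar)
}

#' Periphery-to-core spatial histogram with kurtosis
#'
#' Binned cell positions along the periphery-to-core axis together with the
#' Pearson kurtosis of the raw (unbinned) axis coordinate. Kurtosis is
#' computed from positions, not bin counts, so the bin width affects display
#' only.
#'
#' @slot breaks half-open bin edges \code{[lo, hi)} in um.
#' @slot counts cells per bin; sums to \code{nCells}.
#' @slot nCells number of positions.
#' @slot kurtosis Pearson kurtosis m4/m2^2 (normal = 3, uniform = 1.8).
#' @slot excessKurtosis \code{kurtosis - 3}, reported for transparency.
#' @export
setClass("SpatialHistogram",
  representation(
    breaks = "numeric", counts = "integer", nCells = "integer",
    kurtosis = "numeric", excessKurtosis = "numeric"
  )
)

setValidity("SpatialHistogram", function(object) {
  msg <- character()
  if (sum(object@counts) != object@nCells)
    msg <- c(msg, "bin counts must sum to nCells")
  if (length(object@breaks) != length(object@counts) + 1L)
    msg <- c(msg, "need one more break than bins")
  if (length(msg)) msg else TRUE
})

#' Result of a cohort-level statistical comparison
#'
#' @slot test test actually applied (e.g. "unpaired t-test",
#'   "Mann-Whitney", "Kruskal-Wallis").
#' @slot groups group labels.
#' @slot statistic test statistic.
#' @slot p two-sided p-value.
#' @slot posthoc data.frame of pairwise post-hoc comparisons (possibly empty).
#' @slot normality per-group normality-gate outcome (p-values of the
#'   D'Agostino-Pearson omnibus test; NA when the gate was not evaluable).
#' @slot gate human-readable description of which analysis path fired.
#' @export
setClass("StatResult",
  representation(
    test = "character", groups = "character", statistic = "numeric",
    p = "numeric", posthoc = "data.frame", normality = "numeric",
    gate = "character"
  ),
  prototype(posthoc = data.frame(), normality = numeric(), gate = "")
)

setValidity("StatResult", function(object) {
  if (length(object@p) == 1L && is.finite(object@p) &&
      (object@p < 0 || object@p > 1))
    return("p must lie in [0, 1]")
  TRUE
})
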