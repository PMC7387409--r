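# Preprocessing and detection: the computational stand-in for the
# interactive plugin chain used on the real microscope data (projection,
# debleaching, rigid drift correction, spot detection, contour
# segmentation, vessel counting).

#' Maximum-intensity projection over z
#'
#' @param stack a \code{\linkS4class{TimeLapseStack}}.
#' @return a \code{\linkS4class{ProjectedSeries}} whose every pixel is the
#'   maximum over z of the corresponding voxels.
#' @export
maxProject <- function(stack) {
  stopIfNot(is(stack, "TimeLapseStack"), "stack must be a TimeLapseStack")
  validObject(stack)
  d <- dim(stack@voxels)
  out <- array(0, dim = d[c(1L, 3L, 4L, 5L)])
  out[] <- stack@voxels[, 1L, , , ]
  if (d[2L] > 1L) for (z in 2L:d[2L]) {
    out[] <- pmax(out, stack@voxels[, z, , , ])
  }
  ProjectedSeries(out, pixelSize = stack@pixelSize,
                  frameInterval = stack@frameInterval,
                  channels = stack@channels)
}

.channelIndex <- function(series, channel) {
  if (is.character(channel)) {
    i <- match(channel, series@channels)
    stopIfNot(!is.na(i), paste0("unknown channel: ", channel))
    i
  } else as.integer(channel)
}

#' Photobleaching correction by mono-exponential flattening
#'
#' Fits a single exponential to the frame-mean intensity of one channel and
#' rescales each frame so the corrected frame means are flat; the first
#' frame is left unchanged. An already-flat series passes through
#' untouched (fitted decay ~ 0).
#'
#' @param series a \code{\linkS4class{ProjectedSeries}} with >= 3 frames.
#' @param channel channel label or index to correct.
#' @return a \code{ProjectedSeries} with the channel rescaled; the fitted
#'   per-frame decay rate is attached as attribute \code{"decayRate"}.
#' @export
debleach <- function(series, channel = "GFP") {
  stopIfNot(is(series, "ProjectedSeries"), "series must be a ProjectedSeries")
  nt <- nFrames(series)
  stopIfNot(nt >= 3L, "debleaching needs at least 3 frames")
  ci <- .channelIndex(series, channel)
  mu <- vapply(seq_len(nt),
               function(t) mean(series@frames[t, ci, , ]), numeric(1L))
  stopIfNot(all(mu > 0), "non-positive frame means: cannot fit decay")
  tt <- seq_len(nt) - 1
  fit <- stats::lm(log(mu) ~ tt)
  b <- stats::coef(fit)[[2L]]
  scale <- exp(-b * tt)  # fitted(0)/fitted(t); first frame scale = 1
  out <- series
  for (t in seq_len(nt))
    out@frames[t, ci, , ] <- series@frames[t, ci, , ] * scale[t]
  attr(out, "decayRate") <- -b
  out
}

# integer-pixel translation between two frames by phase correlation
.phaseShift <- function(ref, frame) {
  if (stats::sd(frame) == 0 || stats::sd(ref) == 0) {
    warning("degenerate (constant) frame: assuming zero shift")
    return(c(0L, 0L))
  }
  R <- stats::fft(frame) * Conj(stats::fft(ref))
  R <- R / pmax(Mod(R), 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  idx <- which.max(r)
  h <- nrow(ref); w <- ncol(ref)
  dy <- (idx - 1L) %% h
  dx <- (idx - 1L) %/% h
  if (dy > h / 2) dy <- dy - h
  if (dx > w / 2) dx <- dx - w
  c(as.integer(dx), as.integer(dy))
}

#' Rigid (translation) registration of a time series
#'
#' Estimates an integer-pixel translation of every frame relative to a
#' reference frame by phase correlation on one channel, and applies the
#' correcting shift to all channels identically. Rotation is not modelled.
#'
#' @param series a \code{\linkS4class{ProjectedSeries}}.
#' @param reference reference frame index; its shift is (0, 0).
#' @param channel channel used for the estimate.
#' @return list with \code{series} (corrected) and \code{shifts}, an
#'   \code{nFrames x 2} integer matrix of estimated (dx, dy) frame shifts
#'   (the correction applied is their negation).
#' @export
rigidRegister <- function(series, reference = 1L, channel = "GFP") {
  stopIfNot(is(series, "ProjectedSeries"), "series must be a ProjectedSeries")
  nt <- nFrames(series)
  stopIfNot(reference >= 1L && reference <= nt, "invalid reference frame")
  ci <- .channelIndex(series, channel)
  ref <- series@frames[reference, ci, , ]
  shifts <- matrix(0L, nt, 2L, dimnames = list(NULL, c("dx", "dy")))
  out <- series
  for (t in seq_len(nt)) {
    if (t == reference) next
    s <- .phaseShift(ref, series@frames[t, ci, , ])
    shifts[t, ] <- s
    if (any(s != 0L)) {
      for (ch in seq_along(series@channels))
        out@frames[t, ch, , ] <-
          .circShift(series@frames[t, ch, , ], -s[1L], -s[2L])
    }
  }
  list(series = out, shifts = shifts)
}

.frameDetections <- function(img, pxSize, smoothSigmaUm, threshold,
                             thresholdValue, minAreaPx) {
  empty <- data.frame(x_um = numeric(), y_um = numeric(),
                      peak = numeric(), area_px = integer())
  if (all(img == 0) || stats::sd(img) == 0) return(empty)
  sigmaPx <- smoothSigmaUm / pxSize[1L]
  sm <- if (sigmaPx > 0) EBImage::gblur(img, sigma = sigmaPx) else img
  if (threshold == "otsu") {
    mx <- max(sm)
    th <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  } else th <- thresholdValue
  bw <- sm > th
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  idx <- which(bw, arr.ind = TRUE)
  labs <- lab[idx]
  wts <- sm[idx]
  area <- tabulate(labs, nlab)
  keep <- which(area >= minAreaPx)
  if (!length(keep)) return(empty)
  sw <- vapply(keep, function(l) sum(wts[labs == l]), numeric(1L))
  # intensity-weighted centroids, 0-based pixel convention, reported in um
  cy <- vapply(keep, function(l) {
    s <- labs == l; sum((idx[s, 1L] - 1) * wts[s])
  }, numeric(1L)) / sw
  cx <- vapply(keep, function(l) {
    s <- labs == l; sum((idx[s, 2L] - 1) * wts[s])
  }, numeric(1L)) / sw
  peak <- vapply(keep, function(l) max(wts[labs == l]), numeric(1L))
  data.frame(x_um = cx * pxSize[1L], y_um = cy * pxSize[2L],
             peak = peak, area_px = area[keep])
}

#' Detect cell centroids by smoothing, thresholding and labelling
#'
#' Gaussian-smooths each frame of the chosen channel, thresholds it (Otsu by
#' default, so detections are invariant under global intensity scaling),
#' labels connected components, drops those below a minimum area, and
#' reports intensity-weighted centroids in micrometres.
#'
#' @param series a \code{\linkS4class{ProjectedSeries}}.
#' @param channel channel to detect in.
#' @param smoothSigmaUm Gaussian smoothing sigma in um (default half a
#'   typical 5-um cell radius).
#' @param threshold \code{"otsu"} or \code{"absolute"}.
#' @param thresholdValue absolute threshold (used when
#'   \code{threshold = "absolute"}).
#' @param minAreaPx minimum component area in pixels; the default is the
#'   area of a 3-um-radius disk at the series calibration.
#' @return data.frame (frame, x_um, y_um, peak, area_px); empty frames give
#'   no rows, not an error.
#' @export
detectSpots <- function(series, channel = "GFP", smoothSigmaUm = 2.5,
                        threshold = c("otsu", "absolute"),
                        thresholdValue = NA_real_,
                        minAreaPx = NULL) {
  stopIfNot(is(series, "ProjectedSeries"), "series must be a ProjectedSeries")
  stopIfNot(smoothSigmaUm >= 0, "smoothSigmaUm must be >= 0")
  threshold <- match.arg(threshold)
  if (threshold == "absolute")
    stopIfNot(is.finite(thresholdValue), "absolute threshold needs a value")
  px <- series@pixelSize
  if (is.null(minAreaPx)) minAreaPx <- pi * 3^2 / prod(px)
  ci <- .channelIndex(series, channel)
  res <- lapply(seq_len(nFrames(series)), function(t) {
    d <- .frameDetections(series@frames[t, ci, , ], px, smoothSigmaUm,
                          threshold, thresholdValue, minAreaPx)
    if (nrow(d)) cbind(frame = t, d)
    else cbind(frame = integer(), d)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# full ellipse axes (um) from second-order central moments of a pixel set
.ellipseAxes <- function(rows, cols, pxSize) {
  xs <- (cols - 1) * pxSize[1L]; ys <- (rows - 1) * pxSize[2L]
  cxx <- stats::var(xs) * (length(xs) - 1) / length(xs)
  cyy <- stats::var(ys) * (length(ys) - 1) / length(ys)
  cxy <- stats::cov(xs, ys) * (length(xs) - 1) / length(xs)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  # for a solid ellipse with semi-axes a >= b, eigenvalues are a^2/4, b^2/4
  c(major = 4 * sqrt(ev[1L]), minor = 4 * sqrt(ev[2L]))
}

#' Segment cell contours around detections and fit ellipse axes
#'
#' For each detection a square window is cut around the centroid, locally
#' thresholded (Otsu), and the connected component containing the centre is
#' kept. Fitted-ellipse axes come from second-order region moments.
#' Components touching the window border, or empty windows, are recorded as
#' failures and excluded from morphology statistics.
#'
#' @param series a \code{\linkS4class{ProjectedSeries}}.
#' @param detections data.frame as returned by \code{\link{detectSpots}}.
#' @param channel channel to segment in.
#' @param windowUm window half-width in um.
#' @return list with \code{contours} (list of
#'   \code{\linkS4class{ContourMask}}) and \code{failures} (data.frame of
#'   detections without a valid contour, with a reason).
#' @export
segmentContours <- function(series, detections, channel = "GFP",
                            windowUm = 12) {
  stopIfNot(is(series, "ProjectedSeries"), "series must be a ProjectedSeries")
  px <- series@pixelSize
  d <- dim(series@frames)
  contours <- list()
  failures <- data.frame(frame = integer(), x_um = numeric(),
                         y_um = numeric(), reason = character())
  fail <- function(row, why) {
    failures[nrow(failures) + 1L, ] <<-
      list(row$frame, row$x_um, row$y_um, why)
  }
  ci <- .channelIndex(series, channel)
  rw <- round(windowUm / px[1L])
  for (i in seq_len(nrow(detections))) {
    det <- detections[i, ]
    cx <- round(det$x_um / px[1L]) + 1L
    cy <- round(det$y_um / px[2L]) + 1L
    xs <- max(1L, cx - rw):min(d[4L], cx + rw)
    ys <- max(1L, cy - rw):min(d[3L], cy + rw)
    win <- series@frames[det$frame, ci, ys, xs]
    if (all(win == 0) || stats::sd(win) == 0) { fail(det, "blank"); next }
    mx <- max(win)
    th <- EBImage::otsu(EBImage::Image(win / mx), range = c(0, 1)) * mx
    lab <- EBImage::bwlabel(win > th)
    centreLab <- lab[cy - ys[1L] + 1L, cx - xs[1L] + 1L]
    if (centreLab == 0L) { fail(det, "no component at centre"); next }
    comp <- lab == centreLab
    if (any(comp[1L, ]) || any(comp[nrow(comp), ]) ||
        any(comp[, 1L]) || any(comp[, ncol(comp)])) {
      fail(det, "touches window border"); next
    }
    pix <- which(comp, arr.ind = TRUE)
    if (nrow(pix) < 4L) { fail(det, "degenerate region"); next }
    ax <- .ellipseAxes(pix[, 1L], pix[, 2L], px)
    if (ax["minor"] <= 0) { fail(det, "degenerate region"); next }
    contours[[length(contours) + 1L]] <- new("ContourMask",
      frame = as.integer(det$frame),
      cellId = sprintf("f%d_d%d", det$frame, i),
      mask = comp, offset = c(xs[1L] - 1L, ys[1L] - 1L),
      majorUm = unname(ax["major"]), minorUm = unname(ax["minor"]))
  }
  list(contours = contours, failures = failures)
}

#' Count cells in a single 2D field
#'
#' Single-frame counterpart of \code{\link{detectSpots}} for
#' immunofluorescence fields; cells closer than the detector's resolution
#' merge into one detection (logged as a limitation, not an error).
#'
#' @param image 2D numeric matrix (y, x) or logical mask.
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @param smoothSigmaUm,threshold,thresholdValue,minAreaPx as in
#'   \code{\link{detectSpots}}.
#' @return list with \code{count} and \code{positions} (x_um, y_um).
#' @export
countCells <- function(image, pixelSize = 1, smoothSigmaUm = 1,
                       threshold = c("otsu", "absolute"),
                       thresholdValue = NA_real_, minAreaPx = 4) {
  threshold <- match.arg(threshold)
  if (is.logical(image)) {
    image <- image * 1
    # binary masks need no contrast threshold
    threshold <- "absolute"; thresholdValue <- 0.5; smoothSigmaUm <- 0
  }
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  d <- .frameDetections(image, pixelSize, smoothSigmaUm, threshold,
                        thresholdValue, minAreaPx)
  list(count = nrow(d), positions = d[, c("x_um", "y_um")])
}

#' Count vessels in a CD31 field
#'
#' Thresholds the field (Otsu on positive signal) and counts connected
#' components at or above a minimum area.
#'
#' @param image 2D numeric matrix or logical mask.
#' @param minAreaPx minimum component area in pixels.
#' @return integer vessel count for the field of view.
#' @export
countVessels <- function(image, minAreaPx = 10) {
  if (is.logical(image)) bw <- image
  else {
    if (all(image == 0) || stats::sd(image) == 0) return(0L)
    mx <- max(image)
    th <- EBImage::otsu(EBImage::Image(image / mx), range = c(0, 1)) * mx
    bw <- image > th
  }
  if (!any(bw)) return(0L)
  lab <- EBImage::bwlabel(bw)
  sum(tabulate(lab[lab > 0], max(lab)) >= minAreaPx)
}
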