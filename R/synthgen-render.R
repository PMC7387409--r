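# Rendering of synthetic multi-channel time-lapse stacks.
#
# Cells are drawn as isotropic Gaussian blobs in the GFP channel; the
# mCherry channel fills the tumor core and an SHG-like channel draws
# fibrous streaks in the collagen band. Photobleaching multiplies blob
# amplitude geometrically per frame; stage drift shifts whole frames
# circularly (so registration can recover it exactly and correction is
# lossless); noise is Poisson shot noise plus additive Gaussian read noise.

.addBlob <- function(frame, cxPx, cyPx, sigmaPx, amp) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(5 * sigmaPx)
  xs <- max(1L, floor(cxPx - r)):min(w, ceiling(cxPx + r))
  ys <- max(1L, floor(cyPx - r)):min(h, ceiling(cyPx + r))
  if (!length(xs) || !length(ys)) return(frame)
  gx <- exp(-((xs - cxPx)^2) / (2 * sigmaPx^2))
  gy <- exp(-((ys - cyPx)^2) / (2 * sigmaPx^2))
  frame[ys, xs] <- frame[ys, xs] + amp * outer(gy, gx)
  frame
}

.circShift <- function(m, dx, dy) {
  # positive dx moves content toward larger x (columns), dy toward larger y
  h <- nrow(m); w <- ncol(m)
  dx <- ((dx %% w) + w) %% w
  dy <- ((dy %% h) + h) %% h
  if (dx) m <- m[, c((w - dx + 1L):w, 1L:(w - dx)), drop = FALSE]
  if (dy) m <- m[c((h - dy + 1L):h, 1L:(h - dy)), , drop = FALSE]
  m
}

#' Logical masks of the two tumor compartments
#'
#' @param geometry a \code{\linkS4class{SceneGeometry}}.
#' @return a logical (height x width) matrix; \code{peripheryMask} is TRUE on
#'   the collagen band (columns with 0-based index \code{< peripheryWidthPx}),
#'   \code{coreMask} on its complement, so the two tile the field.
#' @export
peripheryMask <- function(geometry) {
  h <- geometry@fieldSize[1L]; w <- geometry@fieldSize[2L]
  matrix(rep(seq_len(w) - 1L < geometry@peripheryWidthPx, each = h), h, w)
}

#' @rdname peripheryMask
#' @export
coreMask <- function(geometry) !peripheryMask(geometry)

#' Render a time-lapse stack from simulated tracks
#'
#' @param trackSet a \code{\linkS4class{TrackSet}} of trajectories in um.
#' @param geometry a \code{\linkS4class{SceneGeometry}}.
#' @param cellRadius apparent cell radius in um (blob sigma is half of it).
#' @param bleachRate per-frame fractional intensity loss in \code{[0, 1)};
#'   blob amplitude in frame t is scaled by \code{(1 - bleachRate)^(t-1)}, so
#'   frame-mean GFP intensity decays geometrically before noise.
#' @param drift integer per-frame absolute stage shifts, an
#'   \code{nFrames x 2} matrix of (dx, dy) pixels applied circularly to every
#'   channel of the frame; NULL for none.
#' @param noise list with \code{poissonScale} (photons per intensity unit;
#'   0 disables shot noise) and \code{gaussianSd} (additive read noise sd).
#' @param seed integer seed (noise only; rendering is deterministic).
#' @param amplitude peak blob intensity before bleaching.
#' @param nFrames frames to render; defaults to the longest track.
#' @return a list with \code{stack} (a single-z
#'   \code{\linkS4class{TimeLapseStack}} with channels GFP, mCherry, SHG) and
#'   \code{groundTruth} (true per-frame centroids in um, drift, bleach rate).
#' @export
renderTimelapse <- function(trackSet, geometry = SceneGeometry(),
                            cellRadius = 5, bleachRate = 0, drift = NULL,
                            noise = list(poissonScale = 0, gaussianSd = 0),
                            seed = 1L, amplitude = 100,
                            nFrames = NULL) {
  stopIfNot(is(trackSet, "TrackSet"), "trackSet must be a TrackSet")
  validObject(geometry)
  stopIfNot(bleachRate >= 0 && bleachRate < 1,
            "bleachRate must lie in [0, 1)")
  h <- geometry@fieldSize[1L]; w <- geometry@fieldSize[2L]
  px <- geometry@pixelSize
  if (is.null(nFrames)) {
    nFrames <- if (nTracks(trackSet))
      max(vapply(tracks(trackSet), nFrames, integer(1L))) else 1L
  }
  nFrames <- as.integer(nFrames)
  if (is.null(drift)) drift <- matrix(0L, nFrames, 2L)
  drift <- matrix(as.integer(drift), ncol = 2L)
  stopIfNot(nrow(drift) == nFrames, "one drift row per frame")

  # per-frame cell positions in pixels (0-based convention, origin top-left)
  cells <- lapply(tracks(trackSet), function(tr) {
    cx <- tr@x / px[1L]; cy <- tr@y / px[2L]
    if (any(cx < 0 | cx >= w | cy < 0 | cy >= h))
      stop("cell outside field: ", tr@id, call. = FALSE)
    cbind(frame = tr@frame, cx = cx, cy = cy)
  })

  sigmaPx <- cellRadius / 2 / px[1L]
  core <- coreMask(geometry)
  peri <- peripheryMask(geometry)

  mch <- matrix(0, h, w); mch[core] <- 50
  shg <- withSeed(subSeed(seed, 99L), .renderFibers(h, w, peri))

  vox <- array(0, dim = c(nFrames, 1L, 3L, h, w))
  for (t in seq_len(nFrames)) {
    gfp <- matrix(0, h, w)
    amp <- amplitude * (1 - bleachRate)^(t - 1)
    for (cl in cells) {
      i <- match(t, cl[, "frame"])
      if (!is.na(i))
        gfp <- .addBlob(gfp, cl[i, "cx"] + 1, cl[i, "cy"] + 1, sigmaPx, amp)
    }
    fr <- list(gfp, mch, shg)
    if (any(drift[t, ] != 0L))
      fr <- lapply(fr, .circShift, dx = drift[t, 1L], dy = drift[t, 2L])
    for (ch in 1:3) vox[t, 1L, ch, , ] <- fr[[ch]]
  }

  ps <- noise$poissonScale %||% 0
  gs <- noise$gaussianSd %||% 0
  if (ps > 0 || gs > 0) {
    vox <- withSeed(subSeed(seed, 7L), {
      v <- vox
      if (ps > 0) v[] <- stats::rpois(length(v), v * ps) / ps
      if (gs > 0) v[] <- pmax(0, v + stats::rnorm(length(v), 0, gs))
      v
    })
  }

  truth <- do.call(rbind, c(Map(function(tr, cl) {
    data.frame(cell_id = tr@id, frame = cl[, "frame"],
               x_um = tr@x, y_um = tr@y, region = tr@region,
               stringsAsFactors = FALSE)
  }, tracks(trackSet), cells), list(make.row.names = FALSE)))

  list(stack = TimeLapseStack(vox, pixelSize = px,
                              sliceDepth = geometry@sliceDepth,
                              frameInterval = geometry@frameInterval,
                              channels = c("GFP", "mCherry", "SHG")),
       groundTruth = list(positions = truth, drift = drift,
                          bleachRate = bleachRate))
}

# fibrous streaks confined to the collagen band
.renderFibers <- function(h, w, periMask, nFibers = 12L, amp = 40) {
  shg <- matrix(0, h, w)
  bandW <- sum(periMask[1L, ])
  if (bandW == 0L) return(shg)
  for (i in seq_len(nFibers)) {
    y0 <- stats::runif(1L, 1, h); x0 <- stats::runif(1L, 1, bandW)
    ang <- stats::rnorm(1L, pi / 2, 0.3)  # roughly along the band
    len <- stats::runif(1L, h / 4, h)
    tt <- seq(0, len, by = 0.5)
    xs <- round(x0 + tt * cos(ang)); ys <- round(y0 + tt * sin(ang))
    ok <- xs >= 1 & xs <= bandW & ys >= 1 & ys <= h
    shg[cbind(ys[ok], xs[ok])] <- amp
  }
  shg[!periMask] <- 0
  shg
}

#' Generate a binary immunofluorescence mask with known cell placement
#'
#' Places \code{nCells} disk-shaped cells with x (periphery-to-core)
#' coordinates drawn from a stated family and uniform y, rejecting overlaps,
#' and paints them into a binary mask. Used to test position extraction and
#' the spatial-kurtosis analysis against ground truth.
#'
#' @param nCells number of cells (>= 0).
#' @param field (height, width) in pixels.
#' @param depthDistribution \code{"uniform"} over the field width, or
#'   \code{"beta"} with shape parameters \code{betaShape} scaled to the
#'   width (core-concentrated for shape1 > shape2).
#' @param betaShape length-2 shape parameters for the beta family.
#' @param cellRadiusPx painted disk radius in pixels.
#' @param seed integer seed.
#' @param maxTries placement retries per cell before failing.
#' @return list with \code{mask} (logical matrix), \code{positions}
#'   (data.frame x_px, y_px of true centres).
#' @export
generateSpatialMask <- function(nCells, field = c(512L, 512L),
                                depthDistribution = c("uniform", "beta"),
                                betaShape = c(5, 2), cellRadiusPx = 3L,
                                seed = 1L, maxTries = 200L) {
  depthDistribution <- match.arg(depthDistribution)
  stopIfNot(nCells >= 0, "nCells must be >= 0")
  h <- field[1L]; w <- field[2L]
  mask <- matrix(FALSE, h, w)
  if (nCells == 0L)
    return(list(mask = mask,
                positions = data.frame(x_px = numeric(), y_px = numeric())))
  r <- cellRadiusPx
  pos <- withSeed(seed, {
    xs <- numeric(nCells); ys <- numeric(nCells)
    for (i in seq_len(nCells)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        x <- switch(depthDistribution,
          uniform = stats::runif(1L, r + 1, w - r),
          beta = r + 1 + stats::rbeta(1L, betaShape[1L], betaShape[2L]) *
                   (w - 2 * r - 2))
        y <- stats::runif(1L, r + 1, h - r)
        if (i == 1L ||
            all((xs[seq_len(i - 1L)] - x)^2 +
                (ys[seq_len(i - 1L)] - y)^2 > (2 * r + 2)^2)) {
          xs[i] <- x; ys[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed)
        stop("could not place ", nCells, " disjoint cells in the field",
             call. = FALSE)
    }
    data.frame(x_px = xs, y_px = ys)
  })
  for (i in seq_len(nCells)) {
    cx <- pos$x_px[i]; cy <- pos$y_px[i]
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    mask[ys, xs] <- mask[ys, xs] | (d2 <= r^2)
  }
  list(mask = mask, positions = pos)
}

#' Generate per-field vessel and cell counts with a target rank correlation
#'
#' Emulates paired counts of CD31-positive vessels and GFP-positive T cells
#' over fields of view, with a configurable Spearman correlation. For
#' \code{|targetRho| = 1} a strictly monotone construction is used; otherwise
#' counts are drawn through a Gaussian copula whose latent Pearson
#' correlation is chosen to give the requested Spearman value.
#'
#' @param nFields number of fields (>= 3).
#' @param targetRho target Spearman correlation in \code{[-1, 1]}.
#' @param seed integer seed.
#' @param lambdaVessel,lambdaCell Poisson means of the marginal counts.
#' @return data.frame (field, vessels, cells); counts are non-negative
#'   integers.
#' @export
generateVesselFields <- function(nFields, targetRho = 0.7, seed = 1L,
                                 lambdaVessel = 10, lambdaCell = 40) {
  stopIfNot(nFields >= 3, "nFields must be >= 3")
  stopIfNot(is.finite(targetRho) && abs(targetRho) <= 1,
            "targetRho must lie in [-1, 1]")
  if (abs(targetRho) == 1) {
    v <- seq_len(nFields) + 2L
    cells <- 3L * v + 5L
    if (targetRho < 0) cells <- rev(cells)
    return(data.frame(field = seq_len(nFields), vessels = v, cells = cells))
  }
  r <- 2 * sin(pi * targetRho / 6)  # latent Pearson for Gaussian copula
  withSeed(seed, {
    z1 <- stats::rnorm(nFields)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(nFields)
    data.frame(field = seq_len(nFields),
               vessels = stats::qpois(stats::pnorm(z1), lambdaVessel),
               cells = stats::qpois(stats::pnorm(z2), lambdaCell))
  })
}
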