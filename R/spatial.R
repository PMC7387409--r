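# Spatial-distribution analysis: positions from binary masks, the
# periphery-to-core histogram with Pearson kurtosis, region counts, and
# the vessel-cell rank correlation.

#' Extract cell positions from a binary mask
#'
#' One position per connected foreground component (binary centroid),
#' reported in micrometres.
#'
#' @param mask logical (height x width) matrix.
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @return data.frame (x_um, y_um), one row per component.
#' @export
maskPositions <- function(mask, pixelSize = 1) {
  stopIfNot(is.logical(mask) && is.matrix(mask), "mask must be logical")
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  if (!any(mask)) return(data.frame(x_um = numeric(), y_um = numeric()))
  lab <- EBImage::bwlabel(mask)
  idx <- which(mask, arr.ind = TRUE)
  labs <- lab[idx]
  cx <- tapply((idx[, 2L] - 1) * pixelSize[1L], labs, mean)
  cy <- tapply((idx[, 1L] - 1) * pixelSize[2L], labs, mean)
  data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy))
}

#' Pearson kurtosis of positions along the periphery-to-core axis
#'
#' K = m4 / m2^2 with population central moments: no excess subtraction and
#' no small-sample bias correction (normal = 3, uniform = 1.8, symmetric
#' two-point = 1, the Pearson lower bound). Higher K indicates cells
#' distributed further toward the tumor core relative to a uniform spread.
#' Invariant under affine rescaling of the axis.
#'
#' @param x numeric axis coordinates (periphery-to-core, increasing x), or a
#'   positions data.frame with an \code{x_um} column.
#' @return the kurtosis K.
#' @export
spatialKurtosis <- function(x) {
  if (is.data.frame(x)) x <- x$x_um
  stopIfNot(length(x) >= 4L, "kurtosis needs at least 4 positions")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  stopIfNot(m2 > 0, "kurtosis undefined for zero-variance positions")
  mean((x - m)^4) / m2^2
}

#' Periphery-to-core spatial histogram
#'
#' Bins positions along the periphery-to-core axis and attaches the Pearson
#' kurtosis of the raw coordinates. The kurtosis is computed from the
#' unbinned positions, so the bin width affects display only; counts always
#' conserve the number of cells.
#'
#' @param positions data.frame with \code{x_um} (and typically
#'   \code{y_um}).
#' @param binUm bin width in um.
#' @param range axis range (lo, hi); defaults to snapping the data range to
#'   whole bins.
#' @return a \code{\linkS4class{SpatialHistogram}}.
#' @export
spatialHistogram <- function(positions, binUm = 25, range = NULL) {
  x <- positions$x_um
  stopIfNot(length(x) >= 4L, "need at least 4 positions")
  if (is.null(range))
    range <- c(floor(min(x) / binUm), ceiling(max(x) / binUm) + 1e-9) * binUm
  breaks <- seq(range[1L], range[2L], by = binUm)
  if (breaks[length(breaks)] < range[2L])
    breaks <- c(breaks, breaks[length(breaks)] + binUm)
  # half-open [lo, hi) bins
  counts <- tabulate(findInterval(x, breaks, left.open = FALSE),
                     length(breaks) - 1L)
  k <- spatialKurtosis(x)
  new("SpatialHistogram", breaks = breaks, counts = as.integer(counts),
      nCells = length(x), kurtosis = k, excessKurtosis = k - 3)
}

#' Count cells by tumor compartment
#'
#' @param positions data.frame (x_um, y_um).
#' @param periphery,core disjoint logical (height x width) masks.
#' @param pixelSize um/pixel (scalar or (x, y)).
#' @return data.frame with peritumoral, intratumoral, unassigned and total
#'   counts; total = peritumoral + intratumoral + unassigned.
#' @export
regionCounts <- function(positions, periphery, core, pixelSize = 1) {
  stopIfNot(!any(periphery & core), "masks must be disjoint")
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  h <- nrow(periphery); w <- ncol(periphery)
  col <- floor(positions$x_um / pixelSize[1L]) + 1L
  row <- floor(positions$y_um / pixelSize[2L]) + 1L
  inside <- col >= 1L & col <= w & row >= 1L & row <= h
  nPeri <- sum(periphery[cbind(row[inside], col[inside])])
  nCore <- sum(core[cbind(row[inside], col[inside])])
  data.frame(peritumoral = nPeri, intratumoral = nCore,
             unassigned = nrow(positions) - nPeri - nCore,
             total = nrow(positions))
}

#' Spearman correlation of vessel and cell counts across fields
#'
#' Rank correlation (average ranks on ties) with a two-sided p-value,
#' for paired per-field vessel and T-cell counts.
#'
#' @param fields data.frame with columns \code{vessels} and \code{cells}
#'   (>= 3 rows).
#' @return list with \code{rho} and \code{p}.
#' @export
vesselCellCorrelation <- function(fields) {
  stopIfNot(is.data.frame(fields) && nrow(fields) >= 3L,
            "need at least 3 fields")
  stopIfNot(all(c("vessels", "cells") %in% names(fields)),
            "fields needs columns vessels, cells")
  if (stats::sd(fields$vessels) == 0 || stats::sd(fields$cells) == 0)
    stop("correlation undefined: constant counts", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(fields$vessels, fields$cells, method = "spearman",
                    exact = FALSE, alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
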