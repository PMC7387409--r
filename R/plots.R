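# Standard figures: quadrant scatter, origin-centred track plots,
# periphery-to-core histogram. Base graphics, written as PNG by the
# pipeline.

#' Quadrant scatter of velocity vs meandering index
#'
#' One point per track with the classifier threshold lines; quadrants are
#' labelled Q1 (high v, low MI), Q2 (high v, high MI), Q3 (low, low),
#' Q4 (low v, high MI).
#'
#' @param metrics classified metric table (see \code{\link{classifyBehavior}}).
#' @param thresholds the \code{\linkS4class{ClassifierThresholds}} used.
#' @param main plot title.
#' @return invisibly, NULL; draws on the current device.
#' @export
plotQuadrants <- function(metrics,
                          thresholds = ClassifierThresholds(2.16, 0.45),
                          main = "T-cell behavior quadrants") {
  cols <- c(Q1 = "#D55E00", Q2 = "#0072B2", Q3 = "#999999", Q4 = "#009E73")
  col <- if ("quadrant" %in% names(metrics))
    cols[as.character(metrics$quadrant)] else "#444444"
  graphics::plot(metrics$MI, metrics$v_um_min, pch = 19, cex = 0.6,
                 col = col, xlim = c(0, 1),
                 xlab = "meandering index", ylab = "mean velocity (um/min)",
                 main = main)
  graphics::abline(h = thresholds@vStar, v = thresholds@miStar, lty = 2)
  usr <- graphics::par("usr")
  graphics::text(c(thresholds@miStar / 2,
                   (thresholds@miStar + 1) / 2)[c(1, 2, 1, 2)],
                 rep(c(usr[4L] * 0.97, thresholds@vStar / 2), each = 2L),
                 labels = c("Q1", "Q2", "Q3", "Q4"), font = 2)
  invisible(NULL)
}

#' Origin-centred track plot
#'
#' @param trackSet a \code{\linkS4class{TrackSet}}.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotTracks <- function(trackSet, main = "track plot") {
  tab <- trackPlotCoordinates(trackSet)
  lim <- max(abs(c(tab$x_um, tab$y_um)), 1)
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", main = main)
  graphics::abline(h = 0, v = 0, col = "grey80")
  ids <- unique(tab$cell_id)
  cols <- grDevices::hcl.colors(max(length(ids), 2L), "Dark 3")
  for (i in seq_along(ids)) {
    g <- tab[tab$cell_id == ids[i], ]
    graphics::lines(g$x_um, g$y_um, col = cols[i])
  }
  invisible(NULL)
}

#' Plot a periphery-to-core spatial histogram
#'
#' @param hist a \code{\linkS4class{SpatialHistogram}}.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotSpatialHistogram <- function(hist, main = "periphery-to-core histogram") {
  mids <- (hist@breaks[-1L] + hist@breaks[-length(hist@breaks)]) / 2
  graphics::barplot(hist@counts, names.arg = round(mids), space = 0,
                    xlab = "distance along periphery-to-core axis (um)",
                    ylab = "cells per bin",
                    main = sprintf("%s (kurtosis %.3g)", main,
                                   hist@kurtosis))
  invisible(NULL)
}
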