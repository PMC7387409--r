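# File-format interfaces: multi-page TIFF stacks, track tables, configs.

#' Write a time-lapse stack as multi-page TIFF
#'
#' Pages are ordered t-major, then z, then channel (TZC), one grayscale
#' 16-bit page each; physical calibration and axis order are written to a
#' JSON sidecar at \code{<path>.json}.
#'
#' @param stack a \code{\linkS4class{TimeLapseStack}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeStackTIFF <- function(stack, path) {
  stopIfNot(is(stack, "TimeLapseStack"), "stack must be a TimeLapseStack")
  d <- dim(stack@voxels)
  mx <- max(stack@voxels, 1)
  pages <- list()
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L]))
    for (ch in seq_len(d[3L]))
      pages[[length(pages) + 1L]] <- stack@voxels[t, z, ch, , ] / mx
  jsonlite::write_json(list(
    order = "TZCYX", dims = d, scale = mx,
    pixelSize = stack@pixelSize, sliceDepth = stack@sliceDepth,
    frameInterval = stack@frameInterval, channels = stack@channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a stack written by \code{\link{writeStackTIFF}}
#'
#' @param path TIFF file (with its \code{<path>.json} calibration sidecar).
#' @return a \code{\linkS4class{TimeLapseStack}}.
#' @export
readStackTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  d <- meta$dims
  vox <- array(0, dim = d)
  i <- 1L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L]))
    for (ch in seq_len(d[3L])) {
      vox[t, z, ch, , ] <- pages[[i]] * meta$scale
      i <- i + 1L
    }
  TimeLapseStack(vox, pixelSize = meta$pixelSize,
                 sliceDepth = meta$sliceDepth,
                 frameInterval = meta$frameInterval,
                 channels = meta$channels)
}

#' Write tracks as a CSV table
#'
#' Columns: cell_id, frame, t_min, x_um, y_um, region.
#'
#' @param trackSet a \code{\linkS4class{TrackSet}}.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeTracksCSV <- function(trackSet, path) {
  utils::write.csv(trackCoords(trackSet), path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by \code{\link{writeTracksCSV}}
#'
#' @param path CSV with columns cell_id, frame, x_um, y_um and optionally
#'   t_min and region.
#' @param frameInterval minutes per frame, used when t_min is absent.
#' @param mouse,arm metadata for the returned set.
#' @return a \code{\linkS4class{TrackSet}}.
#' @export
readTracksCSV <- function(path, frameInterval = 0.5,
                          mouse = NA_character_, arm = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(all(c("cell_id", "frame", "x_um", "y_um") %in% names(df)),
            "track CSV needs cell_id, frame, x_um, y_um")
  trs <- lapply(split(df, df$cell_id), function(g) {
    g <- g[order(g$frame), ]
    Track(id = g$cell_id[1L], frame = g$frame, x = g$x_um, y = g$y_um,
          frameInterval = frameInterval,
          time = if ("t_min" %in% names(g)) g$t_min
                 else (g$frame - 1) * frameInterval,
          region = if ("region" %in% names(g)) g$region[1L]
                   else "unassigned")
  })
  TrackSet(unname(trs), mouse = mouse, arm = arm)
}
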