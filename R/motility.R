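# Per-track motility metrics, morphology, and the four-quadrant
# behavioural classification.

#' Per-track motility metrics
#'
#' Computes, for each track: straight-line displacement d (origin to
#' terminus, um), total path length L (sum of consecutive steps, um),
#' duration T (min), mean velocity v = d / T (um/min, the displacement-based
#' definition used throughout), meandering index MI = d / L (1 for a
#' completely linear, directional track; defined as 0 when L = 0), and a
#' supplementary conventional path speed L / T.
#'
#' @param x a \code{\linkS4class{Track}} or \code{\linkS4class{TrackSet}}.
#' @return a data.frame with one row per track: cell_id, region, n_points,
#'   d_um, L_um, T_min, v_um_min, MI, path_speed_um_min (supplementary).
#'   For a \code{TrackSet}, mouse and arm columns are prepended.
#' @examples
#' tr <- Track("c1", 1:11, x = seq(0, 10, 1), y = rep(0, 11))
#' trackMetrics(tr)  # d = L = 10, v = 2, MI = 1
#' @export
trackMetrics <- function(x) {
  if (is(x, "TrackSet")) {
    if (nTracks(x) == 0L)
      return(cbind(data.frame(mouse = character(), arm = character()),
                   .emptyMetrics()))
    tab <- do.call(rbind, c(lapply(tracks(x), trackMetrics),
                            list(make.row.names = FALSE)))
    return(cbind(mouse = x@mouse, arm = x@arm, tab))
  }
  stopIfNot(is(x, "Track"), "x must be a Track or TrackSet")
  n <- nFrames(x)
  stopIfNot(n >= 2L, "metrics need at least 2 points")
  T <- x@time[n] - x@time[1L]
  stopIfNot(T > 0, "track duration must be positive")
  d <- sqrt((x@x[n] - x@x[1L])^2 + (x@y[n] - x@y[1L])^2)
  L <- sum(sqrt(diff(x@x)^2 + diff(x@y)^2))
  data.frame(cell_id = x@id, region = x@region, n_points = n,
             d_um = d, L_um = L, T_min = T, v_um_min = d / T,
             MI = if (L == 0) 0 else d / L,
             path_speed_um_min = L / T,
             stringsAsFactors = FALSE)
}

.emptyMetrics <- function() {
  data.frame(cell_id = character(), region = character(),
             n_points = integer(), d_um = numeric(), L_um = numeric(),
             T_min = numeric(), v_um_min = numeric(), MI = numeric(),
             path_speed_um_min = numeric(), stringsAsFactors = FALSE)
}

#' Combine metrics over several track sets
#'
#' Sets whose tracks were all excluded contribute no rows.
#'
#' @param trackSets list of \code{\linkS4class{TrackSet}} objects.
#' @return row-bound metric table (see \code{\link{trackMetrics}}).
#' @export
cohortMetrics <- function(trackSets) {
  do.call(rbind, c(lapply(trackSets, trackMetrics),
                   list(make.row.names = FALSE)))
}

#' Origin-centred track-plot coordinates
#'
#' Translates every track so its first point is the origin, preserving the
#' track shape exactly; used for track plots showing migration relative to
#' the point of origin.
#'
#' @param trackSet a \code{\linkS4class{TrackSet}}.
#' @return data.frame (cell_id, frame, t_min, x_um, y_um, region) with each
#'   track starting at (0, 0).
#' @export
trackPlotCoordinates <- function(trackSet) {
  stopIfNot(is(trackSet, "TrackSet"), "trackSet must be a TrackSet")
  tab <- do.call(rbind, c(lapply(tracks(trackSet), function(tr) {
    df <- trackCoords(tr)
    df$x_um <- df$x_um - df$x_um[1L]
    df$y_um <- df$y_um - df$y_um[1L]
    df
  }), list(make.row.names = FALSE)))
  tab
}

#' Cohort-wide behavioural thresholds
#'
#' The quadrant thresholds are the unweighted means of the per-track mean
#' velocity and meandering index pooled over all tracks from all arms,
#' following the published choice of cohort-wide means (which gave
#' 2.16 um/min and 0.45 there).
#'
#' @param metrics metric table from \code{\link{trackMetrics}} /
#'   \code{\link{cohortMetrics}} (>= 1 row).
#' @return a \code{\linkS4class{ClassifierThresholds}}.
#' @export
cohortThresholds <- function(metrics) {
  stopIfNot(is.data.frame(metrics) && nrow(metrics) >= 1L,
            "need at least one track")
  ClassifierThresholds(vStar = mean(metrics$v_um_min),
                       miStar = mean(metrics$MI))
}

#' Four-quadrant behavioural classification
#'
#' Divides the velocity-vs-meandering plane into four behavioural groups:
#' Q1 actively migrating cells returning toward their origin (high v, low
#' MI); Q2 directional, sustained movement (high v, high MI); Q3 low
#' motility (low v, low MI); Q4 non-sustained motility (low v, high MI).
#' Values exactly at a threshold count as "high" (>=).
#'
#' @param metrics metric table with columns v_um_min and MI.
#' @param thresholds a \code{\linkS4class{ClassifierThresholds}}; defaults
#'   to the published cohort-wide values 2.16 um/min and 0.45.
#' @return the metric table with a \code{quadrant} factor column
#'   (levels Q1..Q4) appended; every track lands in exactly one quadrant.
#' @export
classifyBehavior <- function(metrics,
                             thresholds = ClassifierThresholds(2.16, 0.45)) {
  stopIfNot(is(thresholds, "ClassifierThresholds"),
            "thresholds must be a ClassifierThresholds")
  validObject(thresholds)
  v <- metrics$v_um_min; mi <- metrics$MI
  stopIfNot(all(is.finite(v)) && all(is.finite(mi)),
            "metrics must be finite")
  highV <- v >= thresholds@vStar
  highMI <- mi >= thresholds@miStar
  q <- ifelse(highV, ifelse(highMI, "Q2", "Q1"),
              ifelse(highMI, "Q4", "Q3"))
  metrics$quadrant <- factor(q, levels = c("Q1", "Q2", "Q3", "Q4"))
  metrics
}

#' Elongation statistics over a contour series
#'
#' Summarises the per-frame elongation index E = major/minor of one cell's
#' contours: the mean E and, as a measure of how rapidly the morphology
#' changes over the imaging time-course, the temporal standard deviation of
#' E (an extension beyond the published mean-only readout, labelled as
#' such).
#'
#' @param contours list of \code{\linkS4class{ContourMask}} for one cell.
#' @return data.frame (n_frames, E_mean, E_sd).
#' @export
elongationStats <- function(contours) {
  e <- vapply(contours, elongationIndex, numeric(1L))
  data.frame(n_frames = length(e),
             E_mean = if (length(e)) mean(e) else NA_real_,
             E_sd = if (length(e) > 1L) stats::sd(e) else NA_real_)
}
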