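# Shared fixture builders (all programmatic; no stored data).

# rasterise a filled, rotated ellipse into a single-frame ProjectedSeries
rasterEllipse <- function(a, b, size = 4L * a + 21L, angle = 0,
                          value = 100) {
  cx <- (size + 1) / 2
  img <- array(0, dim = c(1L, 1L, size, size))
  ca <- cos(angle); sa <- sin(angle)
  for (yy in seq_len(size)) for (xx in seq_len(size)) {
    u <- (xx - cx) * ca + (yy - cx) * sa
    v <- -(xx - cx) * sa + (yy - cx) * ca
    if ((u / a)^2 + (v / b)^2 <= 1) img[1L, 1L, yy, xx] <- value
  }
  ProjectedSeries(img, pixelSize = 1, frameInterval = 0.5,
                  channels = "GFP")
}

# a well-separated grid of slow confined walkers for round-trip tests
gridWalkers <- function(nx = 5L, ny = 4L, spacing = 64, margin = 32,
                        nFrames = 61L, speed = 2, radius = 8, seed = 1L) {
  trs <- list()
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    start <- c(margin + (ix - 1L) * spacing, margin + (iy - 1L) * spacing)
    trs[[k]] <- simulateTrack(
      MotionModel("confined_brownian", speed, confinementRadius = radius),
      nFrames, 0.5, start = start, seed = subSeed(seed, k),
      id = sprintf("true_%02d", k))
  }
  TrackSet(trs)
}

# greedy bipartite matching of detections to truth within a radius;
# returns matched distances (one per matched pair)
matchDetections <- function(det, truth, radius) {
  if (!nrow(det) || !nrow(truth)) return(numeric())
  d2 <- outer(det$x_um, truth$x_um, "-")^2 +
        outer(det$y_um, truth$y_um, "-")^2
  matches <- numeric()
  repeat {
    i <- which.min(d2)
    if (!length(i) || d2[i] > radius^2) break
    r <- (i - 1L) %% nrow(d2) + 1L
    c <- (i - 1L) %/% nrow(d2) + 1L
    matches <- c(matches, sqrt(d2[i]))
    d2[r, ] <- Inf
    d2[, c] <- Inf
    if (all(is.infinite(d2))) break
  }
  matches
}

# random Track with n points, for property tests
randomTrack <- function(n, id = "r1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Track(id, seq_len(n), x = cumsum(stats::rnorm(n, 0, 3)),
        y = cumsum(stats::rnorm(n, 0, 3)), frameInterval = 0.5)
}
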