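# Trajectory simulators for the four motility regimes.
#
# All simulators are pure functions of (model, seed): the RNG state is
# localised, so identical inputs give identical tracks.

#' Simulate one cell trajectory
#'
#' Generates a 2D trajectory under the given motion model. Simulation is in
#' the projection plane, matching the downstream analysis which operates on
#' maximum-intensity projections.
#'
#' Regimes:
#' \describe{
#'   \item{ballistic}{constant heading, constant step \code{speedScale * dt};
#'     the resulting track is perfectly collinear.}
#'   \item{confined_brownian}{isotropic Gaussian steps, hard-confined to a
#'     disk of \code{confinementRadius} around the start (proposals leaving
#'     the disk are resampled, then radially clipped).}
#'   \item{levy}{step lengths from a truncated power law with density
#'     proportional to \code{l^-levyExponent} on
#'     \code{[l0, truncationStep]}, headings isotropic with optional
#'     persistence blending; clusters of small steps interspersed with long
#'     relocations.}
#'   \item{stationary_probing}{centroid jitter (sd 0.5 um) around the start
#'     with periodic small protrusion excursions; displacement stays near
#'     zero.}
#' }
#'
#' @param model a \code{\linkS4class{MotionModel}}.
#' @param nFrames number of positions (>= 2).
#' @param dt frame interval in minutes (> 0).
#' @param start (x, y) start position in um.
#' @param seed integer seed.
#' @param id cell identifier for the returned track.
#' @param region region label attached to the track.
#' @return a \code{\linkS4class{Track}} with exactly \code{nFrames} points.
#' @examples
#' tr <- simulateTrack(MotionModel("ballistic", 5), nFrames = 61,
#'                     dt = 0.5, seed = 1)
#' nFrames(tr)
#' @export
simulateTrack <- function(model, nFrames, dt, start = c(0, 0), seed = 1L,
                          id = "cell_1", region = "unassigned") {
  stopIfNot(is(model, "MotionModel"), "model must be a MotionModel")
  validObject(model)
  stopIfNot(is.finite(nFrames) && nFrames >= 2,
            "nFrames must be at least 2")
  stopIfNot(is.finite(dt) && dt > 0, "dt must be > 0")
  stopIfNot(all(is.finite(start)) && length(start) == 2L,
            "start must be two finite coordinates")
  nFrames <- as.integer(nFrames)

  xy <- withSeed(seed, switch(model@kind,
    ballistic = .simBallistic(model, nFrames, dt, start),
    confined_brownian = .simConfined(model, nFrames, dt, start),
    levy = .simLevy(model, nFrames, dt, start),
    stationary_probing = .simProbing(model, nFrames, dt, start)
  ))

  Track(id = id, frame = seq_len(nFrames), x = xy[, 1L], y = xy[, 2L],
        frameInterval = dt, region = region)
}

.simBallistic <- function(model, n, dt, start) {
  theta <- stats::runif(1L, 0, 2 * pi)
  step <- model@speedScale * dt
  k <- seq_len(n) - 1
  cbind(start[1L] + k * step * cos(theta),
        start[2L] + k * step * sin(theta))
}

.simConfined <- function(model, n, dt, start) {
  # sd chosen so the mean 2D step length is speedScale * dt
  sdStep <- model@speedScale * dt / sqrt(pi / 2)
  r <- model@confinementRadius
  xy <- matrix(0, n, 2L)
  xy[1L, ] <- start
  for (i in 2L:n) {
    prop <- xy[i - 1L, ] + stats::rnorm(2L, 0, sdStep)
    tries <- 0L
    while (sqrt(sum((prop - start)^2)) > r && tries < 50L) {
      prop <- xy[i - 1L, ] + stats::rnorm(2L, 0, sdStep)
      tries <- tries + 1L
    }
    d <- sqrt(sum((prop - start)^2))
    if (d > r) prop <- start + (prop - start) * (r / d)  # radial clip
    xy[i, ] <- prop
  }
  xy
}

# inverse-CDF sample from density ~ l^-a on [l0, l1]
.rtruncPareto <- function(n, a, l0, l1) {
  u <- stats::runif(n)
  if (abs(a - 1) < 1e-12) {
    exp(log(l0) + u * (log(l1) - log(l0)))
  } else {
    p <- 1 - a
    (l0^p + u * (l1^p - l0^p))^(1 / p)
  }
}

.simLevy <- function(model, n, dt, start) {
  l0 <- 0.5 * model@speedScale * dt
  l1 <- max(model@truncationStep, l0 * 1.0001)
  len <- .rtruncPareto(n - 1L, model@levyExponent, l0, l1)
  # persistence-blended headings: wrapped-normal increments
  sdTheta <- (1 - model@persistence) * pi
  theta <- cumsum(c(stats::runif(1L, 0, 2 * pi),
                    stats::rnorm(n - 2L, 0, sdTheta)))
  steps <- cbind(len * cos(theta), len * sin(theta))
  rbind(start, sweep(apply(steps, 2L, cumsum), 2L, start, "+"))
}

.simProbing <- function(model, n, dt, start, jitterSd = 0.5,
                        protrusionEvery = 10L, protrusionUm = 1.5) {
  xy <- matrix(stats::rnorm(2L * n, 0, jitterSd), n, 2L)
  xy <- sweep(xy, 2L, start, "+")
  xy[1L, ] <- start
  # brief protrusion excursions, returning to baseline the next frame
  at <- seq(protrusionEvery, n - 1L, by = protrusionEvery)
  if (length(at)) {
    ang <- stats::runif(length(at), 0, 2 * pi)
    xy[at, 1L] <- xy[at, 1L] + protrusionUm * cos(ang)
    xy[at, 2L] <- xy[at, 2L] + protrusionUm * sin(ang)
  }
  xy
}
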