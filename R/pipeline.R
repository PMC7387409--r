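# End-to-end orchestration: synthetic cohort -> rendering -> preprocessing
# -> detection -> tracking -> metrics/classification -> spatial analysis
# -> cohort statistics, with a manifest recording every parameter and seed.

#' Default demonstration configuration
#'
#' A compact three-arm synthetic study (control, monotherapy at speed
#' multiplier 0.4, combination at 0.5; treated arms carry more cells) that
#' runs the full pipeline in a few minutes on one CPU.
#'
#' @param seed master seed.
#' @return a nested configuration list; see \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(nMice = 2L, cellsControl = 6L, cellsTreated = 9L,
                  baseSpeed = 4.6, nFrames = 41L),
    geometry = list(fieldSize = c(192L, 192L), pixelSize = 1,
                    frameInterval = 0.5, peripheryWidthPx = 48L),
    render = list(cellRadius = 5, bleachRate = 0.02,
                  driftStepPx = c(1L, 0L), driftEvery = 10L,
                  noise = list(poissonScale = 0, gaussianSd = 0.5)),
    detect = list(smoothSigmaUm = 2.5, threshold = "otsu", minAreaPx = 12),
    # gate just above the Levy truncation bound (25 um) so genuine long
    # relocations are not split into track fragments
    track = list(maxStepUm = 26, maxGap = 1L, minTimepoints = 5L),
    thresholds = "auto",
    spatial = list(nCells = 150L, depthDistribution = "beta",
                   binUm = 25, nFields = 60L, targetRho = 0.7)
  )
}

.stage <- function(name, manifest, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s (completed stages: %s)", name,
                 conditionMessage(e),
                 paste(manifest$stages, collapse = ", ")), call. = FALSE))
  res
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: trajectory simulation; stack rendering with
#' photobleaching, stage drift and noise; maximum-intensity projection,
#' debleaching and rigid registration; spot detection; track linking,
#' track-length exclusion and region assignment; motility metrics and
#' quadrant classification; spatial-distribution analysis (mask positions,
#' periphery-to-core kurtosis, region counts, vessel-cell correlation); and
#' cohort statistics (Kruskal-Wallis with Dunn's post-hoc on per-track
#' velocities across arms, mean +/- SEM summaries). All tables, figures and
#' a JSON manifest are written under \code{outDir}. Reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config configuration list (see \code{\link{demoConfig}}) or the
#'   path to a YAML file holding one.
#' @param outDir output directory (created if missing).
#' @param seed optional master-seed override.
#' @return invisibly, a list with the classified metric table, thresholds,
#'   spatial results, statistics and the manifest.
#' @export
runPipeline <- function(config = demoConfig(), outDir = tempfile("ivrun"),
                        seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ivmotility",
                   version = as.character(utils::packageVersion("ivmotility")),
                   seed = config$seed, config = config, stages = character())
  noteStage <- function(s) manifest$stages <<- c(manifest$stages, s)

  geo <- do.call(SceneGeometry, config$geometry)

  ## 1. synthetic cohort ----------------------------------------------------
  sim <- .stage("synthgen", manifest, {
    spec <- defaultCohortSpec(seed = config$seed,
                              nMice = config$cohort$nMice,
                              cellsControl = config$cohort$cellsControl,
                              cellsTreated = config$cohort$cellsTreated,
                              baseSpeed = config$cohort$baseSpeed)
    simulateCohort(spec, geo, nFrames = config$cohort$nFrames,
                   reflect = TRUE)
  })
  noteStage("synthgen")

  ## 2. render + preprocess + detect ---------------------------------------
  rcfg <- config$render
  nFr <- config$cohort$nFrames
  drift <- matrix(0L, nFr, 2L)
  if (!is.null(rcfg$driftStepPx) && rcfg$driftEvery > 0L) {
    k <- (seq_len(nFr) - 1L) %/% rcfg$driftEvery
    drift[, 1L] <- k * rcfg$driftStepPx[1L]
    drift[, 2L] <- k * rcfg$driftStepPx[2L]
  }
  detections <- .stage("imgproc", manifest, {
    lapply(sim$trackSets, function(ts) {
      rend <- renderTimelapse(ts, geo, cellRadius = rcfg$cellRadius,
                              bleachRate = rcfg$bleachRate, drift = drift,
                              noise = rcfg$noise,
                              seed = subSeed(config$seed, 11L))
      proj <- maxProject(rend$stack)
      if (rcfg$bleachRate > 0) proj <- debleach(proj, "GFP")
      # drift is estimated on the static collagen (SHG) structure
      reg <- rigidRegister(proj, reference = 1L, channel = "SHG")
      detectSpots(reg$series, channel = "GFP",
                  smoothSigmaUm = config$detect$smoothSigmaUm,
                  threshold = config$detect$threshold,
                  minAreaPx = config$detect$minAreaPx)
    })
  })
  noteStage("imgproc")

  ## 3. tracking ------------------------------------------------------------
  trackSets <- .stage("tracking", manifest, {
    peri <- peripheryMask(geo); core <- coreMask(geo)
    out <- Map(function(det, ts) {
      linked <- linkDetections(det, maxStepUm = config$track$maxStepUm,
                               maxGap = config$track$maxGap,
                               frameInterval = geo@frameInterval,
                               mouse = ts@mouse, arm = ts@arm)
      linked <- filterShortTracks(linked, config$track$minTimepoints)
      assignRegion(linked, peri, core, pixelSize = geo@pixelSize)
    }, detections, sim$trackSets)
    out
  })
  noteStage("tracking")

  ## 4. metrics + classification ---------------------------------------------
  motres <- .stage("motility", manifest, {
    metrics <- cohortMetrics(trackSets)
    stopIfNot(nrow(metrics) > 0L, "no tracks survived filtering")
    thr <- if (identical(config$thresholds, "auto")) cohortThresholds(metrics)
           else ClassifierThresholds(config$thresholds[[1L]],
                                     config$thresholds[[2L]])
    list(metrics = classifyBehavior(metrics, thr), thresholds = thr)
  })
  noteStage("motility")

  ## 5. spatial analysis -----------------------------------------------------
  spat <- .stage("spatial", manifest, {
    scfg <- config$spatial
    sm <- generateSpatialMask(scfg$nCells, field = geo@fieldSize,
                              depthDistribution = scfg$depthDistribution,
                              seed = subSeed(config$seed, 21L))
    pos <- maskPositions(sm$mask, pixelSize = geo@pixelSize)
    hist <- spatialHistogram(pos, binUm = scfg$binUm)
    rc <- regionCounts(pos, peripheryMask(geo), coreMask(geo),
                       pixelSize = geo@pixelSize)
    vf <- generateVesselFields(scfg$nFields, targetRho = scfg$targetRho,
                               seed = subSeed(config$seed, 22L))
    list(positions = pos, histogram = hist, regionCounts = rc,
         vesselFields = vf, vesselCorrelation = vesselCellCorrelation(vf))
  })
  noteStage("spatial")

  ## 6. cohort statistics ----------------------------------------------------
  stats <- .stage("cohort", manifest, {
    met <- motres$metrics
    byArm <- split(met$v_um_min, met$arm)
    armMeans <- do.call(rbind, lapply(names(byArm), function(a)
      cbind(arm = a, meanSem(byArm[[a]]))))
    testable <- byArm[vapply(byArm, length, integer(1L)) >= 3L]
    kw <- if (length(testable) >= 3L) compareKGroups(testable) else NULL
    list(armVelocity = armMeans,
         armOrdering = armMeans$arm[order(-armMeans$mean)],
         kruskalWallis = kw)
  })
  noteStage("cohort")

  ## outputs ------------------------------------------------------------------
  met <- motres$metrics
  utils::write.csv(met, file.path(outDir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, c(lapply(trackSets, trackCoords),
                                    list(make.row.names = FALSE))),
                   file.path(outDir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$groundTruth, file.path(outDir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(stats$armVelocity,
                   file.path(outDir, "arm_velocity.csv"), row.names = FALSE)
  h <- spat$histogram
  utils::write.csv(data.frame(bin_lo = h@breaks[-length(h@breaks)],
                              bin_hi = h@breaks[-1L], count = h@counts),
                   file.path(outDir, "spatial_histogram.csv"),
                   row.names = FALSE)

  grDevices::png(file.path(outDir, "quadrants.png"), 700, 600)
  plotQuadrants(met, motres$thresholds)
  grDevices::dev.off()
  grDevices::png(file.path(outDir, "track_plot.png"), 600, 600)
  plotTracks(trackSets[[1L]])
  grDevices::dev.off()
  grDevices::png(file.path(outDir, "spatial_histogram.png"), 700, 500)
  plotSpatialHistogram(h)
  grDevices::dev.off()

  manifest$thresholds <- c(vStar = motres$thresholds@vStar,
                           miStar = motres$thresholds@miStar)
  manifest$armOrdering <- stats$armOrdering
  manifest$spatialKurtosis <- h@kurtosis
  manifest$outputs <- list.files(outDir)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  invisible(list(metrics = met, thresholds = motres$thresholds,
                 trackSets = trackSets, spatial = spat, stats = stats,
                 manifest = manifest, outDir = outDir))
}
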