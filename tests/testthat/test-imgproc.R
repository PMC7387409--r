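test_that("maximum projection equals the per-pixel brute-force maximum", {
  set.seed(1)
  vox <- array(runif(2 * 5 * 1 * 8 * 9), dim = c(2, 5, 1, 8, 9))
  st <- TimeLapseStack(vox, channels = "GFP")
  pr <- maxProject(st)
  # exhaustive per-pixel oracle
  for (t in 1:2) for (y in 1:8) for (x in 1:9) {
    expect_identical(pr@frames[t, 1, y, x], max(vox[t, , 1, y, x]))
  }
  # single-z stack projects to the identity
  one <- TimeLapseStack(vox[, 1, , , , drop = FALSE], channels = "GFP")
  expect_equal(as.numeric(maxProject(one)@frames),
               as.numeric(vox[, 1, , , ]))
  # projection is idempotent on its own output
  back <- TimeLapseStack(array(pr@frames, dim = c(2, 1, 1, 8, 9)),
                         channels = "GFP")
  expect_identical(maxProject(back)@frames, pr@frames)
})

test_that("debleaching flattens exponential decay and preserves flat series", {
  geo <- SceneGeometry(c(64L, 64L), 1, peripheryWidthPx = 16L)
  ts <- TrackSet(list(Track("a", 1:30, x = rep(30, 30), y = rep(30, 30))))
  r <- renderTimelapse(ts, geo, cellRadius = 5, bleachRate = 0.02,
                       nFrames = 30)
  pr <- maxProject(r$stack)
  db <- debleach(pr, "GFP")
  mu <- vapply(1:30, function(t) mean(db@frames[t, 1, , ]), numeric(1))
  expect_lt(sd(mu) / mean(mu), 1e-4)
  expect_equal(db@frames[1, 1, , ], pr@frames[1, 1, , ])  # first frame fixed
  expect_equal(attr(db, "decayRate"), -log(0.98), tolerance = 1e-6)

  # already-flat series passes through within numerical tolerance
  flat <- renderTimelapse(ts, geo, cellRadius = 5, nFrames = 10)
  pf <- maxProject(flat$stack)
  df <- debleach(pf, "GFP")
  expect_equal(df@frames, pf@frames, tolerance = 1e-9)

  # decay + mild noise: corrected means have no residual linear trend
  rn <- renderTimelapse(ts, geo, cellRadius = 5, bleachRate = 0.02,
                        noise = list(poissonScale = 0, gaussianSd = 0.02),
                        nFrames = 30, seed = 2)
  dn <- debleach(maxProject(rn$stack), "GFP")
  mun <- vapply(1:30, function(t) mean(dn@frames[t, 1, , ]), numeric(1))
  trend <- coef(lm(mun / mean(mun) ~ seq_along(mun)))[[2]]
  expect_lt(abs(trend), 1e-3)
})

test_that("registration recovers injected integer drift exactly", {
  geo <- SceneGeometry(c(96L, 96L), 1, peripheryWidthPx = 24L)
  ts <- TrackSet(list(Track("a", 1:20, x = rep(40, 20), y = rep(60, 20))))
  drift <- cbind(0:19, -(0:19) %/% 2)
  r <- renderTimelapse(ts, geo, cellRadius = 5, drift = drift)
  reg <- rigidRegister(maxProject(r$stack), reference = 1, channel = "GFP")
  expect_equal(unname(reg$shifts[, "dx"]), drift[, 1])
  expect_equal(unname(reg$shifts[, "dy"]), drift[, 2])
  # corrected series matches an undrifted rendering exactly
  r0 <- renderTimelapse(ts, geo, cellRadius = 5)
  expect_equal(reg$series@frames, maxProject(r0$stack)@frames,
               tolerance = 1e-12)

  # no drift: all shifts zero
  reg0 <- rigidRegister(maxProject(r0$stack))
  expect_true(all(reg0$shifts == 0L))

  # degenerate constant frames: warning, zero shift
  const <- ProjectedSeries(array(1, dim = c(2, 1, 16, 16)), channels = "GFP")
  expect_warning(regc <- rigidRegister(const), "degenerate")
  expect_true(all(regc$shifts == 0L))
})

test_that("spot detection finds well-separated blobs at sub-pixel accuracy", {
  geo <- SceneGeometry(c(128L, 128L), 1, peripheryWidthPx = 32L)
  truth <- data.frame(x_um = c(30, 80, 100), y_um = c(30, 90, 40))
  ts <- TrackSet(lapply(1:3, function(i)
    Track(sprintf("c%d", i), 1, x = truth$x_um[i], y = truth$y_um[i])))
  r <- renderTimelapse(ts, geo, cellRadius = 5,
                       noise = list(poissonScale = 20, gaussianSd = 0.5),
                       seed = 6, nFrames = 1)
  det <- detectSpots(maxProject(r$stack), "GFP")
  expect_equal(nrow(det), 3)
  m <- matchDetections(det, truth, radius = 2)
  expect_length(m, 3)
  expect_true(all(m < 1))

  # blank frame: zero detections, not an error
  blank <- ProjectedSeries(array(0, dim = c(1, 1, 32, 32)), channels = "GFP")
  expect_equal(nrow(detectSpots(blank)), 0)

  # Otsu detections are invariant under global intensity scaling
  pr <- maxProject(r$stack)
  pr5 <- pr; pr5@frames <- pr@frames * 5
  expect_equal(detectSpots(pr5, "GFP")[, c("x_um", "y_um", "area_px")],
               det[, c("x_um", "y_um", "area_px")], tolerance = 1e-12)
})

test_that("contour segmentation recovers analytic ellipse axes", {
  # rasterised disk: axes agree within 5%
  disk <- rasterEllipse(8, 8, size = 41)
  sd1 <- segmentContours(disk, data.frame(frame = 1L, x_um = 20, y_um = 20),
                         windowUm = 15)
  expect_length(sd1$contours, 1)
  cm <- sd1$contours[[1]]
  expect_lt(abs(cm@majorUm / cm@minorUm - 1), 0.05)

  # 16/8 px semi-axes: axis ratio 2.0 within 5%
  ell <- rasterEllipse(16, 8, size = 81)
  se <- segmentContours(ell, data.frame(frame = 1L, x_um = 40, y_um = 40),
                        windowUm = 30)
  expect_length(se$contours, 1)
  expect_equal(elongationIndex(se$contours[[1]]), 2, tolerance = 0.05)

  # detection in a blank region: recorded failure, no mask
  blank <- ProjectedSeries(array(0, dim = c(1, 1, 64, 64)), channels = "GFP")
  sb <- segmentContours(blank, data.frame(frame = 1L, x_um = 30, y_um = 30),
                        windowUm = 10)
  expect_length(sb$contours, 0)
  expect_equal(nrow(sb$failures), 1)
})

test_that("cell and vessel counting follow their ground truth", {
  sm <- generateSpatialMask(50, c(256L, 256L), "uniform", seed = 5)
  cc <- countCells(sm$mask)
  expect_equal(cc$count, 50)
  expect_equal(countCells(matrix(FALSE, 32, 32))$count, 0)

  # two cells closer than the detector resolution merge into one count
  merged <- matrix(0, 64, 64)
  for (ctr in list(c(30, 30), c(30, 34)))
    for (yy in 1:64) for (xx in 1:64)
      if ((xx - ctr[1])^2 + (yy - ctr[2])^2 <= 9)
        merged[yy, xx] <- 100
  expect_equal(countCells(merged > 0)$count, 1)

  # vessels: 7 synthetic blobs; blank field; sub-minimum blob filtered
  vm <- generateSpatialMask(7, c(128L, 128L), "uniform", seed = 11,
                            cellRadiusPx = 4L)
  expect_equal(countVessels(vm$mask, minAreaPx = 10), 7)
  expect_equal(countVessels(matrix(0, 32, 32)), 0)
  tiny <- matrix(FALSE, 32, 32); tiny[10:11, 10:11] <- TRUE
  expect_equal(countVessels(tiny, minAreaPx = 10), 0)
})

test_that("stack TIFF round trip preserves voxels and calibration", {
  set.seed(2)
  vox <- array(runif(2 * 2 * 2 * 16 * 16) * 100, dim = c(2, 2, 2, 16, 16))
  st <- TimeLapseStack(vox, pixelSize = 0.83, sliceDepth = 5.5,
                       frameInterval = 0.5, channels = c("GFP", "mCherry"))
  f <- tempfile(fileext = ".tif")
  writeStackTIFF(st, f)
  back <- readStackTIFF(f)
  expect_equal(back@voxels, vox, tolerance = 1e-3)   # 16-bit quantisation
  expect_equal(back@pixelSize, st@pixelSize)
  expect_identical(back@channels, st@channels)
  unlink(f)
})
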