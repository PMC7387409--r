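test_that("ballistic tracks take equal collinear steps", {
  tr <- simulateTrack(MotionModel("ballistic", 5), nFrames = 61, dt = 0.5,
                      seed = 4)
  steps <- sqrt(diff(tr@x)^2 + diff(tr@y)^2)
  expect_equal(steps, rep(2.5, 60), tolerance = 1e-12)
  # collinearity: cross products of consecutive step vectors vanish
  dx <- diff(tr@x); dy <- diff(tr@y)
  expect_lt(max(abs(dx[-1] * dy[-60] - dx[-60] * dy[-1])), 1e-9)
})

test_that("confined walkers never leave the confinement radius", {
  for (s in 1:20) {
    tr <- simulateTrack(
      MotionModel("confined_brownian", 6, confinementRadius = 10),
      nFrames = 61, dt = 0.5, start = c(30, 40), seed = s)
    expect_lte(max(sqrt((tr@x - 30)^2 + (tr@y - 40)^2)), 10 + 1e-9)
  }
})

test_that("truncated-Levy steps respect the truncation bound", {
  m <- MotionModel("levy", 5, levyExponent = 2, truncationStep = 15)
  for (s in 1:20) {
    tr <- simulateTrack(m, 200, 0.5, seed = s)
    expect_lte(max(sqrt(diff(tr@x)^2 + diff(tr@y)^2)), 15 + 1e-9)
  }
})

test_that("Levy step tail is heavier than Brownian at equal speed scale", {
  # simulator step lengths, pooled over seeds
  stepLengths <- function(kind) {
    unlist(lapply(1:60, function(s) {
      m <- MotionModel(kind, 5, levyExponent = 2, truncationStep = 50,
                       confinementRadius = 1e6)
      tr <- simulateTrack(m, 200, 0.5, seed = s)
      sqrt(diff(tr@x)^2 + diff(tr@y)^2)
    }))
  }
  tailRatio <- function(l) unname(quantile(l, 0.99) / median(l))
  rLevy <- tailRatio(stepLengths("levy"))
  rBrown <- tailRatio(stepLengths("confined_brownian"))
  expect_gt(rLevy, rBrown)

  # independent oracle: resample both step distributions directly
  # (rejection sampling for the truncated power law, Gaussian norms for
  # Brownian), outside the simulator code path
  set.seed(99)
  l0 <- 0.5 * 5 * 0.5; l1 <- 50
  prop <- exp(runif(4e5, log(l0), log(l1)))   # log-uniform proposal
  acc <- runif(4e5) < (prop / l0)^(-2) / (prop / l0)^(-1)
  levyOracle <- prop[acc][1:2e4]
  brownOracle <- sqrt(rnorm(2e4)^2 + rnorm(2e4)^2)
  expect_gt(tailRatio(levyOracle), tailRatio(brownOracle))
})

test_that("stationary probing stays near its origin", {
  tr <- simulateTrack(MotionModel("stationary_probing", 5), 61, 0.5,
                      start = c(10, 10), seed = 2)
  expect_lt(max(sqrt((tr@x - 10)^2 + (tr@y - 10)^2)), 5)
  expect_lt(trackMetrics(tr)$d_um, 5)
})

test_that("simulators are pure functions of (parameters, seed)", {
  for (kind in c("ballistic", "confined_brownian", "levy",
                 "stationary_probing")) {
    m <- MotionModel(kind, 4)
    a <- simulateTrack(m, 50, 0.5, seed = 11)
    b <- simulateTrack(m, 50, 0.5, seed = 11)
    expect_identical(a, b)
    expect_false(identical(a, simulateTrack(m, 50, 0.5, seed = 12)))
  }
})

test_that("simulateTrack validates its inputs", {
  expect_error(simulateTrack(MotionModel("ballistic", 5), 1, 0.5),
               "nFrames")
  expect_error(simulateTrack(MotionModel("ballistic", 5), 10, 0), "dt")
  expect_error(MotionModel("ballistic", NaN), "finite")
  expect_error(MotionModel("levy", 5, levyExponent = 0.9), "levyExponent")
})

test_that("cohort arm means follow the configured speed multipliers", {
  spec <- defaultCohortSpec(seed = 7, nMice = 3, cellsControl = 12,
                            cellsTreated = 20)
  geo <- SceneGeometry(c(256L, 256L), 1, frameInterval = 0.5,
                       peripheryWidthPx = 64L)
  sim <- simulateCohort(spec, geo, nFrames = 61, reflect = TRUE)
  met <- cohortMetrics(sim$trackSets)
  armMean <- tapply(met$v_um_min, met$arm, mean)
  expect_gt(armMean[["control"]], armMean[["combo"]])
  expect_gt(armMean[["combo"]], armMean[["mono"]])
  # ground truth covers every generated track
  expect_setequal(sim$groundTruth$cell_id, met$cell_id)
})

test_that("one arm, one mouse, one cell yields a single track", {
  spec <- CohortSpec(list(list(
    label = "solo", nMice = 1L, cellsPerMouse = 1L,
    models = list(MotionModel("ballistic", 3)), weights = 1,
    speedMultiplier = 1)), seed = 5L)
  sim <- simulateCohort(spec, nFrames = 10)
  expect_length(sim$trackSets, 1L)
  expect_equal(nTracks(sim$trackSets[[1]]), 1L)
  expect_equal(nrow(sim$groundTruth), 1L)
})

test_that("cohort simulation is deterministic and validates arms", {
  spec <- defaultCohortSpec(seed = 3, nMice = 1, cellsControl = 3,
                            cellsTreated = 3)
  expect_identical(simulateCohort(spec, nFrames = 15),
                   simulateCohort(spec, nFrames = 15))
  expect_error(CohortSpec(list()), "arm")
  badArm <- list(label = "x", nMice = 1L, cellsPerMouse = 1L,
                 models = list(MotionModel("ballistic", 1)),
                 weights = 0.7, speedMultiplier = 1)
  expect_error(CohortSpec(list(badArm)), "sum to 1")
})

test_that("rendering places blobs at true centroids and bleaches geometrically", {
  geo <- SceneGeometry(c(96L, 96L), 1, frameInterval = 0.5,
                       peripheryWidthPx = 24L)
  # zero cells, zero noise: GFP identically background
  r0 <- renderTimelapse(TrackSet(list()), geo, nFrames = 3)
  expect_true(all(r0$stack@voxels[, , 1L, , ] == 0))

  # one static cell: per-frame argmax within 1 px of truth
  ts <- TrackSet(list(Track("a", 1:10, x = rep(40, 10), y = rep(60, 10))))
  r1 <- renderTimelapse(ts, geo, cellRadius = 5)
  for (t in 1:10) {
    fr <- r1$stack@voxels[t, 1L, 1L, , ]
    ij <- which(fr == max(fr), arr.ind = TRUE)[1L, ]
    expect_lte(abs(ij[2L] - 1 - 40), 1)
    expect_lte(abs(ij[1L] - 1 - 60), 1)
  }

  # geometric photobleaching, checked against the closed form
  r2 <- renderTimelapse(ts, geo, cellRadius = 5, bleachRate = 0.02,
                        nFrames = 10)
  mu <- vapply(1:10, function(t) mean(r2$stack@voxels[t, 1L, 1L, , ]),
               numeric(1))
  expect_equal(mu / mu[1L], 0.98^(0:9), tolerance = 1e-6)

  # mCherry fills the core, SHG confined to the periphery band
  expect_true(all(r1$stack@voxels[1, 1, 2, , 1:24] == 0))
  expect_true(all(r1$stack@voxels[1, 1, 2, , 25:96] > 0))
  expect_true(all(r1$stack@voxels[1, 1, 3, , 25:96] == 0))

  # a cell outside the field is an input error
  bad <- TrackSet(list(Track("b", 1:2, x = c(10, 200), y = c(10, 10))))
  expect_error(renderTimelapse(bad, geo), "outside")
})

test_that("spatial mask placement matches the requested family", {
  expect_equal(sum(generateSpatialMask(0)$mask), 0)
  sm <- generateSpatialMask(150, c(384L, 384L), "uniform", seed = 8)
  expect_equal(nrow(sm$positions), 150)
  # beta-shaped core-concentrated family has higher kurtosis than uniform;
  # oracle: apply the moment formula to the true positions directly
  momK <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  su <- generateSpatialMask(3000, c(2048L, 2048L), "uniform", seed = 9)
  sb <- generateSpatialMask(3000, c(2048L, 2048L), "beta", seed = 9)
  expect_gt(momK(sb$positions$x_px), momK(su$positions$x_px))
  # overfull field fails after bounded retries
  expect_error(generateSpatialMask(500, c(40L, 40L), seed = 1), "place")
})

test_that("vessel-field generator hits its target rank correlation", {
  v1 <- generateVesselFields(50, 1)
  expect_equal(cor(v1$vessels, v1$cells, method = "spearman"), 1)
  v0 <- generateVesselFields(1000, 0, seed = 3)
  expect_lt(abs(cor(v0$vessels, v0$cells, method = "spearman")), 0.1)
  v3 <- generateVesselFields(3, 0.5, seed = 1)
  expect_equal(nrow(v3), 3)
  expect_true(all(v3$vessels >= 0 & v3$cells >= 0))
  expect_true(all(v3$vessels == round(v3$vessels)))
  v7 <- generateVesselFields(200, 0.7, seed = 2)
  expect_lt(abs(cor(v7$vessels, v7$cells, method = "spearman") - 0.7), 0.15)
  expect_error(generateVesselFields(100, 1.2), "targetRho")
})

test_that("sub-seed splitting is deterministic, order-sensitive and in range", {
  expect_identical(subSeed(1, 2, 3), subSeed(1, 2, 3))
  expect_false(subSeed(1, 2, 3) == subSeed(1, 3, 2))
  s <- vapply(1:500, function(i) subSeed(42, i), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(anyDuplicated(s) > 0)
})
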