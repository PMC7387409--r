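test_that("metric definitions match forced arithmetic on worked tracks", {
  # collinear: 11 points spanning 10 um over 5 min
  lin <- Track("lin", 1:11, x = seq(0, 10, 1), y = rep(0, 11))
  m <- trackMetrics(lin)
  expect_equal(m$d_um, 10, tolerance = 1e-9)
  expect_equal(m$L_um, 10, tolerance = 1e-9)
  expect_equal(m$v_um_min, 2, tolerance = 1e-9)
  expect_identical(m$MI, 1)

  # square loop back to origin: d = 0, L = 40, MI = 0
  sq <- Track("sq", 1:5, x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0),
              frameInterval = 1)
  ms <- trackMetrics(sq)
  expect_equal(ms$d_um, 0)
  expect_equal(ms$L_um, 40, tolerance = 1e-9)
  expect_equal(ms$v_um_min, 0)
  expect_equal(ms$MI, 0)

  # 3-4-5 triangle over 1 min
  tri <- Track("tri", 1:3, x = c(0, 3, 3), y = c(0, 0, 4))
  mt <- trackMetrics(tri)
  expect_equal(mt$d_um, 5, tolerance = 1e-9)
  expect_equal(mt$L_um, 7, tolerance = 1e-9)
  expect_equal(mt$v_um_min, 5, tolerance = 1e-9)
  expect_equal(mt$MI, 5 / 7, tolerance = 1e-9)

  # supplementary path speed is L / T
  expect_equal(mt$path_speed_um_min, 7, tolerance = 1e-9)
})

test_that("velocity and meandering index are rigid-motion invariant", {
  set.seed(123)
  for (i in 1:200) {
    tr <- randomTrack(sample(5:40, 1), "r")
    th <- runif(1, 0, 2 * pi); dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    rot <- tr
    rot@x <- cos(th) * tr@x - sin(th) * tr@y + dx
    rot@y <- sin(th) * tr@x + cos(th) * tr@y + dy
    m0 <- trackMetrics(tr); m1 <- trackMetrics(rot)
    expect_equal(m1$v_um_min, m0$v_um_min, tolerance = 1e-9)
    expect_equal(m1$MI, m0$MI, tolerance = 1e-9)
  }
})

test_that("metric invariants hold on simulated tracks", {
  set.seed(5)
  # L >= d >= 0 and MI in [0, 1] on random tracks
  for (i in 1:100) {
    m <- trackMetrics(randomTrack(sample(3:50, 1), "p"))
    expect_gte(m$L_um, m$d_um - 1e-12)
    expect_gte(m$d_um, 0)
    expect_true(m$MI >= 0 && m$MI <= 1 + 1e-12)
  }
  # degenerate inputs error
  expect_error(trackMetrics(Track("x", 1L, x = 0, y = 0)), "2 points")
  still <- Track("s", 1:2, x = c(0, 0), y = c(0, 0))
  expect_identical(trackMetrics(still)$MI, 0)   # L = 0 convention
})

test_that("track plots preserve shape and recentre the origin", {
  set.seed(9)
  trs <- lapply(1:50, function(i) randomTrack(sample(3:20, 1),
                                              sprintf("t%02d", i)))
  ts <- TrackSet(trs)
  tab <- trackPlotCoordinates(ts)
  for (tr in trs) {
    g <- tab[tab$cell_id == tr@id, ]
    expect_equal(c(g$x_um[1], g$y_um[1]), c(0, 0))
    # pairwise distance oracle
    pre <- dist(cbind(tr@x, tr@y))
    post <- dist(cbind(g$x_um, g$y_um))
    expect_equal(as.numeric(post), as.numeric(pre), tolerance = 1e-12)
  }
})

test_that("quadrant classification matches the nested-conditional oracle", {
  thr <- ClassifierThresholds(2.16, 0.45)
  oracle <- function(v, mi) {
    if (v >= 2.16) { if (mi >= 0.45) "Q2" else "Q1" }
    else { if (mi >= 0.45) "Q4" else "Q3" }
  }
  grid <- expand.grid(v = seq(0.16, 4.66, length.out = 10),
                      MI = seq(0.05, 0.95, length.out = 10))
  # include both threshold-boundary points
  grid <- rbind(grid, data.frame(v = 2.16, MI = 0.2),
                data.frame(v = 1.0, MI = 0.45),
                data.frame(v = 2.16, MI = 0.45))
  met <- data.frame(v_um_min = grid$v, MI = grid$MI)
  out <- classifyBehavior(met, thr)
  expect_identical(as.character(out$quadrant),
                   mapply(oracle, grid$v, grid$MI))
  # the control-cohort means sit in Q1 (fast, low meandering)
  ctrl <- classifyBehavior(data.frame(v_um_min = 4.60, MI = 0.41), thr)
  expect_equal(as.character(ctrl$quadrant), "Q1")
  # exact threshold pair counts as high/high
  onThr <- classifyBehavior(data.frame(v_um_min = 2.16, MI = 0.45), thr)
  expect_equal(as.character(onThr$quadrant), "Q2")
  # every track lands in exactly one quadrant
  expect_false(anyNA(out$quadrant))
  expect_equal(sum(table(out$quadrant)), nrow(out))
})

test_that("cohort thresholds are the unweighted pooled means", {
  met <- data.frame(v_um_min = c(1, 3), MI = c(0.2, 0.6))
  thr <- cohortThresholds(met)
  expect_equal(thr@vStar, 2)
  expect_equal(thr@miStar, 0.4)

  one <- data.frame(v_um_min = 1.7, MI = 0.33)
  t1 <- cohortThresholds(one)
  expect_equal(c(t1@vStar, t1@miStar), c(1.7, 0.33))

  # independent recomputation over a synthetic cohort table
  sim <- simulateCohort(defaultCohortSpec(seed = 4, nMice = 2,
                                          cellsControl = 5,
                                          cellsTreated = 5),
                        nFrames = 21, reflect = TRUE)
  met2 <- cohortMetrics(sim$trackSets)
  thr2 <- cohortThresholds(met2)
  expect_equal(thr2@vStar, sum(met2$v_um_min) / nrow(met2))
  expect_equal(thr2@miStar, sum(met2$MI) / nrow(met2))
  expect_error(cohortThresholds(met2[0, ]), "at least one")
})

test_that("motility regimes separate on meandering index", {
  # ballistic tracks are perfectly straight
  for (s in 1:50) {
    tb <- simulateTrack(MotionModel("ballistic", 5), 61, 0.5, seed = s)
    expect_gt(trackMetrics(tb)$MI, 0.99)
  }
  # confined walkers meander (checked in depth in the acceptance suite)
  mi <- vapply(1:50, function(s) {
    trackMetrics(simulateTrack(
      MotionModel("confined_brownian", 5, confinementRadius = 10),
      61, 0.5, seed = s))$MI
  }, numeric(1))
  expect_gt(mean(mi < 0.3), 0.95)
})

test_that("elongation index is rotation-invariant and >= 1", {
  e0 <- segmentContours(rasterEllipse(24, 12, 101),
                        data.frame(frame = 1L, x_um = 50, y_um = 50),
                        windowUm = 45)$contours[[1]]
  e45 <- segmentContours(rasterEllipse(24, 12, 101, angle = pi / 4),
                         data.frame(frame = 1L, x_um = 50, y_um = 50),
                         windowUm = 45)$contours[[1]]
  expect_equal(elongationIndex(e45), elongationIndex(e0), tolerance = 0.02)
  expect_gte(elongationIndex(e0), 1)
  st <- elongationStats(list(e0, e45))
  expect_equal(st$n_frames, 2)
  expect_gte(st$E_sd, 0)
})
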